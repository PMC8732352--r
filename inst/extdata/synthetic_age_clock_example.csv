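probe_id,weight
cg03207141,-1.701815
cg04248729,-4.828415
cg04818148,0.072245
cg09511546,0.411997
cg03191936,-0.722115
cg03061784,1.516326
cg04604260,-1.45341
cg05828773,-2.736562
cg07151124,0.865636
cg07218051,-1.622786
cg02683481,2.888203
cg01737636,-0.862892
cg07132677,1.311296
cg06008680,0.643851
cg00185658,-1.567678
cg01547422,3.151455
cg02781071,1.285799
cg09828666,0.179521
cg08910116,0.553101
cg04432854,1.358578
cg09543277,0.179666
cg05986501,-5.98618
cg00248034,0.569766
cg06433752,-0.734469
cg07442694,0.370461
cg08728706,1.163647
cg07590915,2.799474
cg07683477,-1.454584
cg00074743,2.605085
cg06650554,0.671696
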