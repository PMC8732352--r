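cg04660509
cg00005261
cg09433562
cg02762282
cg02708216
cg06317307
cg01574771
cg05278958
cg00864879
cg00339448
cg07348978
cg02004898
cg06145248
cg00384214
cg02441823
cg00376660
cg02181546
cg08326554
cg02628801
cg04307768
cg09929826
cg01601884
cg06975805
cg02035611
cg09033401
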