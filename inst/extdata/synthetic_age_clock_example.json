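{"name":"synthetic_age_clock_example","intercept":12.5,"transform":"age_calibration","output_units":"years"}
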