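H01	control
H02	control
H03	control
C01	disease
C02	disease
C03	disease
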