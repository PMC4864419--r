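residue,atom,nucleus,ppm
3,P,31P,-0.04
17,P,31P,-0.19
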