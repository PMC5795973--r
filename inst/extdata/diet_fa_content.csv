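fatty_acid,CH,HO
C14:0,0.14,0.13
C16:0,4.83,7.19
C18:0,0.84,1.83
C18:1n-9,9.47,36.82
C18:2n-6,14.24,16.68
C18:3n-3,0.99,1.21
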