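gene,efficiency_percent
RXRG,84.8
PPARG,93.5
SREBP1,91.5
LEP,92.8
ME1,86.5
SCD,89.6
ACACA,85.2
FASN,85.1
ELOVL6,89.5
ATGL,87.2
HSL,82.8
PLIN1,87.9
G0S2,83.7
ACTB,90.7
PPIA,96.9
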