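gene,effect,fold_change,ci_low,ci_high,p_value,adjusted_p_value
RXRG,breed,1.33,0.90,1.96,0.1424,0.196
RXRG,status,1.27,1.08,1.49,0.0051,0.003
RXRG,diet,1.12,0.91,1.39,0.2720,0.913
PPARG,breed,1.07,0.84,1.36,0.5434,0.213
PPARG,status,1.22,1.07,1.38,0.0029,0.011
PPARG,diet,0.87,0.69,1.09,0.168,0.328
SREBP1,breed,0.87,0.65,1.17,0.3153,0.434
SREBP1,status,1.11,0.93,1.32,0.234,0.322
SREBP1,diet,0.99,0.74,1.33,0.964,0.970
LEP,breed,2.85,1.23,6.64,0.0174,0.075
LEP,status,2.05,1.69,2.48,0.0001,0.001
LEP,diet,0.99,0.68,1.45,0.970,0.970
ME1,breed,1.80,1.03,3.14,0.0427,0.024
ME1,status,1.12,1.00,1.24,0.0470,0.117
ME1,diet,1.18,0.70,2.00,0.4912,0.201
SCD,breed,2.21,1.49,3.27,0.0009,0.003
SCD,status,1.30,1.21,1.40,0.0001,0.001
SCD,diet,1.05,0.74,1.49,0.7304,0.893
ACACA,breed,1.49,0.90,2.46,0.1068,0.147
ACACA,status,2.10,1.87,2.35,0.0001,0.001
ACACA,diet,0.97,0.61,1.53,0.8709,0.871
FASN,breed,1.36,0.95,1.94,0.0820,0.113
FASN,status,1.13,1.02,1.24,0.0196,0.036
FASN,diet,1.16,0.81,1.63,0.3655,0.804
ELOVL6,breed,1.60,1.06,2.40,0.0280,0.039
ELOVL6,status,1.22,1.10,1.37,0.0005,0.001
ELOVL6,diet,0.94,0.68,1.31,0.664,0.809
ATGL,breed,0.89,0.78,1.01,0.0640,0.088
ATGL,status,0.99,0.92,1.07,0.811,0.811
ATGL,diet,1.01,0.92,1.11,0.799,0.879
HSL,breed,0.94,0.79,1.13,0.4870,0.670
HSL,status,0.96,0.89,1.03,0.275,0.336
HSL,diet,0.96,0.82,1.14,0.640,0.805
PLIN1,breed,1.93,0.90,4.14,0.0873,0.120
PLIN1,status,1.07,0.92,1.25,0.399,0.439
PLIN1,diet,0.79,0.63,1.00,0.050,0.046
G0S2,breed,0.89,0.47,1.70,0.6887,0.814
G0S2,status,1.50,1.16,1.95,0.003,0.007
G0S2,diet,0.82,0.51,1.30,0.321,0.501
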