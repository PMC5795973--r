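fatty_acid,type,mean_CH,sem_CH,mean_HO,sem_HO,p_diet,padj_diet,mean_Duroc,sem_Duroc,mean_Iberian,sem_Iberian,p_breed,padj_breed
C14:0,fa,1.24,0.03,1.12,0.03,0.05,ns,1.08,0.03,1.25,0.03,0.005,ns
C16:0,fa,23.68,0.23,20.91,0.23,<0.0001,0.0007,20.32,0.27,24.27,0.20,<0.0001,0.0007
C16:1n-9,fa,0.33,0.01,0.44,0.01,<0.0001,0.0007,0.45,0.02,0.31,0.01,<0.0001,0.0007
C16:1n-7,fa,1.97,0.09,1.60,0.08,0.009,ns,1.97,0.08,1.60,0.10,0.01,ns
C17:0,fa,0.46,0.03,0.39,0.03,0.14,ns,0.41,0.04,0.44,0.03,0.60,ns
C17:1,fa,0.35,0.02,0.28,0.02,0.001,0.04,0.29,0.02,0.34,0.02,0.15,ns
C18:0,fa,13.35,0.24,10.35,0.22,<0.0001,0.0007,10.31,0.26,13.39,0.21,<0.0001,0.0007
C18:1n-9,fa,40.23,0.53,46.49,0.50,<0.0001,0.0007,44.20,0.61,42.53,0.46,0.06,ns
C18:1n-7,fa,1.64,0.13,1.68,0.12,0.78,ns,1.77,0.15,1.55,0.12,0.30,ns
C18:2n-6,fa,13.42,0.22,13.41,0.20,0.99,ns,16.13,0.25,10.70,0.20,<0.0001,0.0007
C18:3n-3,fa,0.84,0.01,0.88,0.01,0.02,ns,1.00,0.02,0.72,0.01,<0.0001,0.0007
C18:4n-3,fa,0.06,0.00,0.07,0.00,0.0004,0.03,0.07,0.00,0.06,0.00,0.01,ns
C20:0,fa,0.22,0.01,0.18,0.01,0.002,ns,0.18,0.01,0.22,0.01,0.01,ns
C20:1n-9,fa,0.97,0.03,1.03,0.02,0.03,ns,0.90,0.03,1.10,0.03,0.0002,0.01
C20:2,fa,0.68,0.01,0.61,0.01,0.004,ns,0.71,0.02,0.59,0.01,0.0002,0.01
C20:4n-6,fa,0.22,0.01,0.22,0.01,0.72,ns,0.26,0.01,0.18,0.01,<0.0001,0.0007
C20:3n-3,fa,0.12,0.00,0.11,0.00,0.02,ns,0.12,0.00,0.11,0.00,0.01,ns
C22:4n-6,fa,0.10,0.00,0.09,0.00,0.27,ns,0.10,0.01,0.09,0.00,0.25,ns
C22:5n-3,fa,0.09,0.02,0.09,0.01,0.69,ns,0.07,0.02,0.11,0.01,0.11,ns
C22:6n-3,fa,0.03,0.01,0.05,0.01,0.20,ns,0.04,0.01,0.04,0.01,0.98,ns
SFA,index,38.93,0.55,32.96,0.51,<0.0001,0.0007,32.31,0.61,39.57,0.47,<0.0001,0.0007
MUFA,index,45.13,0.79,51.24,0.73,<0.0001,0.0007,49.28,0.89,47.09,0.72,<0.0001,0.0007
PUFA,index,14.86,0.29,14.93,0.26,0.34,ns,17.79,0.32,12.01,0.26,<0.0001,0.0007
n-6/n-3,ratio,12.0,0.01,11.43,0.01,0.04,ns,12.78,0.01,11.19,0.01,<0.0001,0.0007
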