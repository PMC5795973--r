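fatty_acid,type,mean_CH,sem_CH,mean_HO,sem_HO,p_diet,padj_diet,mean_Duroc,sem_Duroc,mean_Iberian,sem_Iberian,p_breed,padj_breed
C14:0,fa,1.24,0.02,1.18,0.02,0.02,ns,1.15,0.02,1.27,0.02,0.0008,0.05
C16:0,fa,22.57,0.22,20.54,0.20,<0.0001,0.0007,20.38,0.23,22.73,0.18,<0.0001,0.0007
C16:1n-9,fa,0.28,0.01,0.39,0.01,<0.0001,0.0007,0.36,0.02,0.31,0.01,0.02,ns
C16:1n-7,fa,2.57,0.08,2.16,0.07,<0.0001,0.0007,2.28,0.09,2.45,0.07,0.17,ns
C17:0,fa,0.33,0.03,0.41,0.03,0.17,ns,0.33,0.04,0.42,0.03,0.13,ns
C17:1,fa,0.40,0.02,0.31,0.02,0.0009,0.06,0.30,0.03,0.41,0.02,0.0099,ns
C18:0,fa,10.48,0.21,8.79,0.19,<0.0001,0.0007,9.33,0.23,9.94,0.18,0.05,ns
C18:1n-9,fa,44.75,0.51,49.40,0.48,<0.0001,0.0007,47.26,0.57,46.89,0.43,0.64,ns
C18:1n-7,fa,1.84,0.12,1.69,0.11,0.27,ns,1.67,0.13,1.85,0.10,0.34,ns
C18:2n-6,fa,12.11,0.19,11.87,0.17,0.53,ns,13.58,0.21,10.41,0.16,<0.0001,0.0007
C18:3n-3,fa,0.80,0.02,0.80,0.01,0.45,ns,0.87,0.02,0.73,0.02,<0.0001,0.0007
C18:4n-3,fa,0.08,0.00,0.09,0.00,0.0016,ns,0.09,0.00,0.08,0.00,0.26,ns
C20:0,fa,0.16,0.01,0.14,0.00,<0.0001,0.0007,0.15,0.01,0.15,0.01,0.50,ns
C20:1n-9,fa,1.00,0.02,1.04,0.02,0.05,ns,0.91,0.02,1.13,0.02,<0.0001,0.0007
C20:2,fa,0.67,0.01,0.61,0.01,0.0004,0.03,0.68,0.01,0.61,0.01,<0.0001,0.0007
C20:4n-6,fa,0.25,0.01,0.25,0.01,0.56,ns,0.27,0.01,0.23,0.01,0.04,ns
C20:3n-3,fa,0.13,0.00,0.13,0.00,0.03,ns,0.13,0.00,0.11,0.00,0.02,ns
C22:4n-6,fa,0.10,0.00,0.09,0.00,0.05,ns,0.10,0.00,0.10,0.00,0.46,ns
C22:5n-3,fa,0.13,0.01,0.11,0.01,0.30,ns,0.09,0.02,0.15,0.01,0.03,ns
C22:6n-3,fa,0.07,0.01,0.07,0.01,0.43,ns,0.07,0.01,0.07,0.01,0.78,ns
SFA,index,34.78,0.48,31.06,0.44,<0.0001,0.0007,31.33,0.52,34.52,0.42,<0.0001,0.0007
MUFA,index,50.43,0.75,54.68,0.70,<0.0001,0.0007,52.48,0.83,52.63,0.64,0.99,ns
PUFA,index,13.67,0.25,13.41,0.23,0.34,ns,15.20,0.28,11.87,0.22,<0.0001,0.0007
n-6/n-3,ratio,11.56,0.01,10.19,0.01,0.04,ns,11.16,0.01,9.42,0.01,<0.0001,0.0007
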