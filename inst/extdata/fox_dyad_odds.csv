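dyad_type,id_a,id_b,L_a,p_a,L_b,p_b,L_ixn,p_ixn,spatial,temporal,odds_ab,odds_a0,odds_0b,odds_00
RF-AF,AB,MM,-0.09,0.52,0.45,0.15,-0.10,0.86,Random,Random,1.15,1.42,0.82,0.90
RF-AF,FJ,MM,0.45,0.54,-1.83,0.02,-0.55,0.88,Singular avoidance,Solitary trend,0,0.14,1.34,0.85
RF-AF,W,Gh,0.17,0.92,0.76,0.00,1.21,0.00,Singular attraction,Simultaneous,5.62,1.21,0.70,0.80
AF-AF,Gi,Gh,2.35,0.00,2.29,0.00,1.49,0.00,Symmetric attraction,Simultaneous,33,3.66,3.83,0.34
AF-AF,Gi,GK,0.79,0.15,1.78,0.00,-2.11,0.53,Singular attraction,Solitary trend,0,4.99,1.88,0.83
AF-AF,D,LT,1.17,0.16,1.60,0.01,-2.11,0.85,Singular attraction,Solitary trend,0,4.00,2.61,0.80
RF-RF,A,S,0.88,0.00,-0.50,0.00,-0.45,0.30,Asymmetric,Solitary trend,0.84,0.55,2.17,0.89
RF-RF,A,Br,2.13,0.00,-0.42,0.00,-0.70,0.00,Asymmetric,Solitary,2.7,0.53,6.42,0.74
RF-RF,S,LR,1.68,0.00,0.07,0.84,0.66,0.01,Singular attraction,Simultaneous,7.91,0.61,3.85,0.73
RF-RF,S,I,1.33,0.00,-0.47,0.12,-1.51,0.18,Singular attraction,Solitary trend,0,0.55,3.16,0.82
RF-RF,LR,Br,1.15,0.00,1.75,0.00,-2.32,0.01,Symmetric attraction,Solitary,0,4.40,2.84,0.71
RF-RF,I,Br,-1.01,0.10,0.72,0.03,-0.90,0.67,Asymmetric,Solitary trend,0,1.90,0.34,0.92
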