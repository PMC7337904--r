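# Idealized B-form nucleotide templates (heavy atoms, base standard frame).
# Synthetic: generated from standard bond geometry and canonical
# B-form backbone torsions by linked-atom least squares under the
# helical symmetry twist=36.0 deg, rise=3.375 A, x_disp=0.56 A, incl=-6.0 deg.
# Columns: base,atom,x,y,z (Angstrom).  O2' rows are used for RNA strands only.
base,atom,x,y,z
A,N9,-1.2910,4.4980,0.0000
A,C8,0.0240,4.8970,0.0000
A,N7,0.8770,3.9020,0.0000
A,C5,0.0710,2.7710,0.0000
A,C6,0.3690,1.3980,0.0000
A,N6,1.6110,0.9090,0.0000
A,N1,-0.6680,0.5320,0.0000
A,C2,-1.9120,1.0230,0.0000
A,N3,-2.3200,2.2900,0.0000
A,C4,-1.2670,3.1240,0.0000
A,C1',-2.4790,5.3460,0.0000
A,O4',-2.5730,5.9826,-1.2591
A,C2',-2.4006,6.4658,1.0352
A,C3',-3.3502,7.5124,0.4618
A,C4',-3.1597,7.3495,-1.0434
A,C5',-2.4702,8.5793,-1.6375
A,O5',-1.4556,9.0359,-0.7424
A,P,0.0044,9.4302,-1.2948
A,O3',-4.5679,6.9016,0.8902
A,OP1,0.9930,9.3380,-0.1905
A,OP2,-0.0672,10.7394,-1.9920
A,O2',-2.9031,6.0007,2.2711
C,N1,-1.2850,4.5420,0.0000
C,C2,-1.4720,3.1580,0.0000
C,O2,-2.6280,2.7090,0.0000
C,N3,-0.3910,2.3440,0.0000
C,C4,0.8370,2.8680,0.0000
C,N4,1.8750,2.0270,0.0000
C,C5,1.0560,4.2750,0.0000
C,C6,-0.0230,5.0680,0.0000
C,C1',-2.4770,5.4020,0.0000
C,O4',-2.5678,6.0390,-1.2591
C,C2',-2.3930,6.5214,1.0352
C,C3',-3.3372,7.5727,0.4618
C,C4',-3.1475,7.4089,-1.0434
C,C5',-2.4518,8.6352,-1.6375
C,O5',-1.4349,9.0867,-0.7424
C,P,0.0270,9.4736,-1.2948
C,O3',-4.5580,6.9682,0.8902
C,OP1,1.0117,9.3957,-0.1860
C,OP2,-0.0366,10.7860,-1.9866
C,O2',-2.8978,6.0588,2.2711
G,N9,-1.2890,4.5510,0.0000
G,C8,0.0230,4.9620,0.0000
G,N7,0.8700,3.9690,0.0000
G,C5,0.0710,2.8330,0.0000
G,C6,0.4240,1.4600,0.0000
G,O6,1.5540,0.9550,0.0000
G,N1,-0.7000,0.6410,0.0000
G,C2,-1.9990,1.0870,0.0000
G,N2,-2.9490,0.1390,0.0000
G,N3,-2.3420,2.3640,0.0000
G,C4,-1.2650,3.1770,0.0000
G,C1',-2.4770,5.3990,0.0000
G,O4',-2.5710,6.0356,-1.2591
G,C2',-2.3986,6.5188,1.0352
G,C3',-3.3482,7.5654,0.4618
G,C4',-3.1577,7.4025,-1.0434
G,C5',-2.4682,8.6323,-1.6375
G,O5',-1.4536,9.0889,-0.7424
G,P,0.0064,9.4832,-1.2948
G,O3',-4.5659,6.9546,0.8902
G,OP1,0.9904,9.4162,-0.1846
G,OP2,-0.0664,10.7895,-1.9974
G,O2',-2.9011,6.0537,2.2711
T,N1,-1.2840,4.5000,0.0000
T,C2,-1.4620,3.1350,0.0000
T,O2,-2.5620,2.6080,0.0000
T,N3,-0.2980,2.4070,0.0000
T,C4,0.9940,2.8970,0.0000
T,O4,1.9440,2.1190,0.0000
T,C5,1.1060,4.3380,0.0000
T,C7,2.4660,4.9610,0.0000
T,C6,-0.0240,5.0570,0.0000
T,C1',-2.4810,5.3540,0.0000
T,O4',-2.5751,5.9905,-1.2591
T,C2',-2.4029,6.4739,1.0352
T,C3',-3.3527,7.5201,0.4618
T,C4',-3.1622,7.3573,-1.0434
T,C5',-2.4730,8.5873,-1.6375
T,O5',-1.4584,9.0441,-0.7424
T,P,0.0014,9.4388,-1.2948
T,O3',-4.5702,6.9091,0.8902
T,OP1,0.9893,9.3509,-0.1895
T,OP2,-0.0706,10.7476,-1.9926
T,O2',-2.9053,6.0086,2.2711
U,N1,-1.2840,4.5000,0.0000
U,C2,-1.4620,3.1310,0.0000
U,O2,-2.5630,2.6080,0.0000
U,N3,-0.3020,2.3970,0.0000
U,C4,0.9890,2.8840,0.0000
U,O4,1.9350,2.0940,0.0000
U,C5,1.0890,4.3110,0.0000
U,C6,-0.0240,5.0530,0.0000
U,C1',-2.4810,5.3540,0.0000
U,O4',-2.5751,5.9905,-1.2591
U,C2',-2.4029,6.4739,1.0352
U,C3',-3.3527,7.5201,0.4618
U,C4',-3.1622,7.3573,-1.0434
U,C5',-2.4730,8.5873,-1.6375
U,O5',-1.4584,9.0441,-0.7424
U,P,0.0014,9.4388,-1.2948
U,O3',-4.5702,6.9091,0.8902
U,OP1,0.9893,9.3509,-0.1895
U,OP2,-0.0706,10.7476,-1.9926
U,O2',-2.9053,6.0086,2.2711
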