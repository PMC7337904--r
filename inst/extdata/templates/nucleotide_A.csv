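# Idealized A-form nucleotide templates (heavy atoms, base standard frame).
# Synthetic: generated from standard bond geometry and canonical
# A-form backbone torsions by linked-atom least squares under the
# helical symmetry twist=32.7 deg, rise=2.548 A, x_disp=-4.42 A, incl=19.0 deg.
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
A,O4',-2.1370,6.5933,-0.5715
A,C2',-2.9940,5.6345,1.4083
A,C3',-2.3494,6.9795,1.7264
A,C4',-2.3846,7.6954,0.3792
A,C5',-1.4439,8.9020,0.3832
A,O5',-0.1746,8.5151,0.9107
A,P,1.0944,9.4987,0.7907
A,O3',-3.2939,7.5513,2.6320
A,OP1,2.2895,8.8383,1.3745
A,OP2,0.7741,10.8002,1.4300
A,O2',-4.3989,5.7818,1.3750
C,N1,-1.2850,4.5420,0.0000
C,C2,-1.4720,3.1580,0.0000
C,O2,-2.6280,2.7090,0.0000
C,N3,-0.3910,2.3440,0.0000
C,C4,0.8370,2.8680,0.0000
C,N4,1.8750,2.0270,0.0000
C,C5,1.0560,4.2750,0.0000
C,C6,-0.0230,5.0680,0.0000
C,C1',-2.4770,5.4020,0.0000
C,O4',-2.1287,6.6476,-0.5715
C,C2',-2.9906,5.6931,1.4083
C,C3',-2.3391,7.0348,1.7264
C,C4',-2.3707,7.7509,0.3792
C,C5',-1.4239,8.9527,0.3832
C,O5',-0.1566,8.5594,0.9107
C,P,1.1174,9.5365,0.7907
C,O3',-3.2807,7.6114,2.6320
C,OP1,2.3062,8.8752,1.3861
C,OP2,0.8056,10.8377,1.4349
C,O2',-4.3947,5.8475,1.3750
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
G,O4',-2.1350,6.6463,-0.5715
G,C2',-2.9920,5.6875,1.4083
G,C3',-2.3474,7.0325,1.7264
G,C4',-2.3826,7.7484,0.3792
G,C5',-1.4419,8.9550,0.3832
G,O5',-0.1726,8.5681,0.9107
G,P,1.0964,9.5517,0.7907
G,O3',-3.2919,7.6043,2.6320
G,OP1,2.2851,8.9025,1.3996
G,OP2,0.7716,10.8575,1.4187
G,O2',-4.3969,5.8348,1.3750
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
T,O4',-2.1393,6.6014,-0.5715
T,C2',-2.9961,5.6424,1.4083
T,C3',-2.3518,6.9875,1.7264
T,C4',-2.3872,7.7034,0.3792
T,C5',-1.4468,8.9103,0.3832
T,O5',-0.1773,8.5236,0.9107
T,P,1.0914,9.5075,0.7907
T,O3',-3.2964,7.5591,2.6320
T,OP1,2.2856,8.8493,1.3788
T,OP2,0.7702,10.8095,1.4284
T,O2',-4.4010,5.7893,1.3750
U,N1,-1.2840,4.5000,0.0000
U,C2,-1.4620,3.1310,0.0000
U,O2,-2.5630,2.6080,0.0000
U,N3,-0.3020,2.3970,0.0000
U,C4,0.9890,2.8840,0.0000
U,O4,1.9350,2.0940,0.0000
U,C5,1.0890,4.3110,0.0000
U,C6,-0.0240,5.0530,0.0000
U,C1',-2.4810,5.3540,0.0000
U,O4',-2.1393,6.6014,-0.5715
U,C2',-2.9961,5.6424,1.4083
U,C3',-2.3518,6.9875,1.7264
U,C4',-2.3872,7.7034,0.3792
U,C5',-1.4468,8.9103,0.3832
U,O5',-0.1773,8.5236,0.9107
U,P,1.0914,9.5075,0.7907
U,O3',-3.2964,7.5591,2.6320
U,OP1,2.2856,8.8493,1.3788
U,OP2,0.7702,10.8095,1.4284
U,O2',-4.4010,5.7893,1.3750
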