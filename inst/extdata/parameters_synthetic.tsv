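# Synthetic default parameter set for the plant circadian system model.
# Calibrated with this package against published validation targets
# (free-running/mutant periods, photoperiodic hypocotyl lengths); it is a
# stand-in constructed here, not an externally published estimate.
v1	9.4478131317706815
v2	6.4777822742405595
v3	3.107894640202145
v4	1.6424741045689819
v5	2.9146891870024696
K1	0.67583918390588238
K2	3.8959873848373574
K3	3.8448189382040554
K4	0.69683622702230463
K5	1.3144431540624848
K6	0.48611243877746096
K7	4.8483141506322305
K8	1.2419105882651225
K9	29.163232944136155
K10	9.1664886112193251
K11	0.33697437448456297
K12	22.622028842149781
k1L	0.25622524205447722
k1D	0.26357833693595484
k2	0.57801765159875451
k3	0.66337606348578504
k4	0.39963690510292865
k5	0.88095570514349963
p1	1.2985745922176859
p1L	0.28325776609872166
p2	1.1147594801318901
p3	0.69683607405665848
p4	0.99062034507868379
p5	0.31158115984102941
d1	0.75304219152619067
d2D	0.5648571276164861
d2L	0.33509020466545369
d3D	0.43117206189732071
d3L	4.579824766953088
d4D	0.47636844367846942
d4L	0.61247371330088929
d5D	0.010681023226429982
d5L	3.1073419003141209
g1	0.0098784121806477776
g2	0.33709070966471444
Ap3	1.0888421569793587
Am7	2.7221053924483969
Ak7	1
q2	1.3610526962241984
Bp4	1.0171904395075704
Bm8	2.182304704862736
Bk8	1.061436447262273
Cp5	0.33737231378626675
Cm9	3.4805207362770116
Ck9	2.6865090358865484
q1a	0.52462499923514816
q3a	0.22347227267177497
q4a	0.37498156814424272
q1b	0.41456684346744677
q3b	0.34517937760003653
q4b	1.5773089744209958
eta1	1
eta2	1
kmpac	3.8364056450765953
kmpbc	2.2279574588364062
kmpcc	158.27872286621977
kd	0.0012892480752504339
de1	0.14400808319759256
de2	0.44415994923130042
de3	0.54446673196292372
de4	0.67590629382676704
de5	0.054263229974347203
Ctot	1
c_ox	0.20537137331599678
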