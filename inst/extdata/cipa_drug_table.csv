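name,channel,cmax_free_uM,ic50_uM,hill
dofetilide,INaL,0.002,126,1.1
dofetilide,ICaL,0.002,44.5,3.6
dofetilide,INa,0.002,1.36,1.1
dofetilide,IKr,0.002,0.001,0.6
bepridil,INaL,0.033,1.82,1.4
bepridil,ICaL,0.033,2.82,0.65
bepridil,INa,0.033,2.96,1.2
bepridil,IKr,0.033,0.149,0.9
cisapride,INaL,0.0026,9260,6.3
cisapride,ICaL,0.0026,1030,4.8
cisapride,INa,0.0026,1790,0.67
cisapride,IKr,0.0026,0.012,1.3
verapamil,INaL,0.081,24.1,2
verapamil,ICaL,0.081,0.204,1.1
verapamil,INa,0.081,2590,3.5
verapamil,IKr,0.081,0.499,1.1
ranolazine,INaL,1.95,7.94,0.95
ranolazine,ICaL,1.95,900,3.9
ranolazine,INa,1.95,53.3,1.9
ranolazine,IKr,1.95,6.49,0.8
mexiletine,INaL,4.13,9.02,1.4
mexiletine,ICaL,4.13,38.9,1
mexiletine,INa,4.13,26.1,3.8
mexiletine,IKr,4.13,inf,
diltiazem,INaL,0.122,21.6,0.68
diltiazem,ICaL,0.122,0.113,0.72
diltiazem,INa,0.122,36.9,1.4
diltiazem,IKr,0.122,6.57,0.8
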