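isoform,pose_index,delta_g_protein,stderr,n_trajectories
HCN1,1,129.415,0.919,5
HCN1,2,129.931,1.485,5
HCN1,3,128.421,0.672,5
HCN1,4,131.156,0.660,5
HCN2,1,124.573,1.826,5
HCN2,2,123.230,0.874,5
HCN2,3,126.686,1.170,5
HCN2,4,127.466,1.325,5
HCN3,1,129.415,1.483,5
HCN3,2,133.913,2.762,5
HCN3,3,130.151,1.255,5
HCN3,4,133.422,1.087,5
HCN3,5,127.208,1.676,5
HCN3,6,127.777,0.654,5
HCN4,1,125.181,1.642,5
HCN4,2,127.407,1.275,5
HCN4,3,128.306,2.181,5
HCN4,4,129.107,1.250,5
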