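table,parameter,group,n,mean,se
pigments,chl_a,WT,3,0.38,0.02
pigments,chl_a,MT,3,0.07,0.003
pigments,chl_b,WT,3,0.09,0.01
pigments,chl_b,MT,3,0.03,0.003
pigments,chl_total,WT,3,0.46,0.03
pigments,chl_total,MT,3,0.11,0.003
pigments,chl_ab_ratio,WT,3,4.36,0.19
pigments,chl_ab_ratio,MT,3,2.17,0.33
pigments,carotenoids,WT,3,0.14,0.01
pigments,carotenoids,MT,3,0.15,0.01
mr,V_PSI,WT,3,0.193,0.01
mr,V_PSI,MT,3,0.207,0.003
mr,V_PSII_PSI,WT,3,0.015,0.001
mr,V_PSII_PSI,MT,3,0.017,0.001
mr,V_PSII,WT,3,0.208,0.014
mr,V_PSII,MT,3,0.224,0.004
jip,fv_fm,WT,3,0.82,0.01
jip,fv_fm,MT,3,0.73,0.06
jip,psi_o,WT,3,0.70,0.04
jip,psi_o,MT,3,0.43,0.09
jip,delta_Ro,WT,3,0.35,0.02
jip,delta_Ro,MT,3,0.41,0.09
jip,gamma_RC,WT,3,0.50,0.00
jip,gamma_RC,MT,3,0.32,0.06
jip,phi_Eo,WT,3,0.57,0.04
jip,phi_Eo,MT,3,0.32,0.09
jip,phi_Ro,WT,3,0.20,0.03
jip,phi_Ro,MT,3,0.12,0.02
jip,phi_Do,WT,3,0.18,0.01
jip,phi_Do,MT,3,0.27,0.06
jip,RC_CSo,WT,3,3804,240
jip,RC_CSo,MT,3,3149,254
jip,RC_CSM,WT,3,21305,2004
jip,RC_CSM,MT,3,12146,2875
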