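trait,h2,n_train,mean_ebv_train,sd_ebv_train,mean_acc_train,sd_acc_train,n_test,mean_ebv_test,sd_ebv_test,mean_acc_test,sd_acc_test
WG,0.26,494,1.60,5.57,0.86,0.12,187,4.11,5.17,0.80,0.11
Cw,0.25,472,0.10,0.31,0.85,0.12,185,0.19,0.35,0.79,0.12
Pw,0.25,472,-0.03,0.42,0.85,0.12,184,0.21,0.42,0.79,0.12
Mw,0.26,473,-0.02,0.40,0.85,0.12,185,0.20,0.41,0.80,0.11
Nw,0.27,468,0.02,0.27,0.85,0.12,188,0.06,0.23,0.80,0.11
PWG,0.33,473,0.66,7.58,0.85,0.12,115,2.83,7.65,0.81,0.10
Cy,0.31,454,0.13,0.36,0.84,0.13,118,0.29,0.40,0.80,0.11
Py,0.31,455,-0.06,0.55,0.83,0.13,117,0.24,0.53,0.80,0.11
My,0.30,448,-0.05,0.51,0.84,0.12,121,0.25,0.50,0.79,0.11
Ny,0.30,443,0.03,0.30,0.84,0.13,122,0.07,0.26,0.79,0.11
SCaw,0.40,446,-0.22,1.21,0.81,0.14,115,-0.15,1.15,0.75,0.12
BW,0.37,457,0.40,1.35,0.86,0.11,189,0.15,1.25,0.83,0.11
GL,0.49,307,0.17,3.25,0.88,0.10,138,-0.77,4.04,0.88,0.10
WI,NA,479,2.74,13.03,0.85,0.12,185,9.83,13.10,0.80,0.11
FI,NA,465,0.86,12.13,0.84,0.12,130,8.17,11.94,0.77,0.13
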