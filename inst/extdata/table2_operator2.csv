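object,config,ratio,method,operator,isocontour_pct,true_mL,true_mL_alt,measured_mL,error_pct
cylinder1,18.5MBq,NA,spect,2,1,6716,NA,7087,5.52
sphere1,18.5MBq,2.8,spect,2,31,55,NA,207,276.36
sphere2,18.5MBq,7.6,spect,2,13,20.5,21.0,104.5,397.62
sphere3,18.5MBq,9.6,spect,2,19,16,NA,27.4,71.25
sphere4,18.5MBq,19.6,spect,2,8,8,NA,29.2,265.00
cylinder1,37MBq,NA,spect,2,2,6716,NA,6180,-7.98
sphere1,37MBq,6,spect,2,7,55,NA,169.7,208.55
sphere2,37MBq,17,spect,2,3,20.5,21.0,113.7,441.43
sphere3,37MBq,23.4,spect,2,3,16,NA,119.78,648.63
sphere4,37MBq,43.8,spect,2,4,8,NA,53.48,568.50
cylinder1,55.5MBq,NA,spect,2,1,6716,NA,6737,0.31
sphere1,55.5MBq,9.9,spect,2,10,55,NA,159.3,189.64
sphere2,55.5MBq,29.6,spect,2,4,20.5,21.0,85,304.76
sphere3,55.5MBq,38.6,spect,2,7,16,NA,51.5,221.88
sphere4,55.5MBq,73.1,spect,2,6,8,NA,44.1,451.25
cylinder1,74MBq,NA,spect,2,1,6716,NA,6565,-2.10
sphere1,74MBq,16,spect,2,15,55,NA,99.5,80.91
sphere2,74MBq,45,spect,2,6,20.5,21.0,54.1,157.62
sphere3,74MBq,57,spect,2,5,16,NA,42.8,167.50
sphere4,74MBq,114,spect,2,2,8,NA,35.8,347.50
cylinder2,55MBq,NA,spect,2,17,774,NA,887,14.60
cylinder2,116MBq,NA,spect,2,19,774,NA,855,10.47
cylinder3,72MBq,NA,spect,2,21,473,NA,520,9.94
cylinder1,18.5MBq,NA,spect_ct,2,2,6716,NA,6521,-2.90
sphere1,18.5MBq,2.8,spect_ct,2,48,55,NA,57.2,4.00
sphere2,18.5MBq,7.6,spect_ct,2,28,20.5,21.0,24.4,16.19
sphere3,18.5MBq,9.6,spect_ct,2,29,16,NA,16.9,5.62
sphere4,18.5MBq,19.6,spect_ct,2,19,8,NA,10.9,36.25
cylinder1,37MBq,NA,spect_ct,2,1,6716,NA,6700,-0.24
sphere1,37MBq,6,spect_ct,2,34,55,NA,53.56,-2.62
sphere2,37MBq,17,spect_ct,2,23,20.5,21.0,24.34,15.90
sphere3,37MBq,23.4,spect_ct,2,27,16,NA,14.9,-6.88
sphere4,37MBq,43.8,spect_ct,2,33,8,NA,9.8,22.50
cylinder1,55.5MBq,NA,spect_ct,2,1,6716,NA,6737,0.31
sphere1,55.5MBq,9.9,spect_ct,2,35,55,NA,55.7,1.27
sphere2,55.5MBq,29.6,spect_ct,2,25,20.5,21.0,22.7,8.10
sphere3,55.5MBq,38.6,spect_ct,2,36,16,NA,15.5,-3.13
sphere4,55.5MBq,73.1,spect_ct,2,36,8,NA,12,50.00
cylinder1,74MBq,NA,spect_ct,2,1,6716,NA,6565,-2.10
sphere1,74MBq,16,spect_ct,2,32,55,NA,56,1.82
sphere2,74MBq,45,spect_ct,2,23,20.5,21.0,23.7,12.86
sphere3,74MBq,57,spect_ct,2,25,16,NA,17.4,8.75
sphere4,74MBq,114,spect_ct,2,20,8,NA,8.7,8.75
cylinder2,55MBq,NA,spect_ct,2,27,774,NA,801,3.49
cylinder2,116MBq,NA,spect_ct,2,29,774,NA,775,0.13
cylinder3,72MBq,NA,spect_ct,2,27,473,NA,481,1.69
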