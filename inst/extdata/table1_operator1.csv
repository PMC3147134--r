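object,config,ratio,method,operator,isocontour_pct,true_mL,true_mL_alt,measured_mL,error_pct
cylinder1,18.5MBq,NA,spect,1,2,6716,NA,6521,-2.90
sphere1,18.5MBq,2.8,spect,1,42,55,NA,75.45,37.18
sphere2,18.5MBq,7.6,spect,1,31,20.5,21.0,22.35,6.43
sphere3,18.5MBq,9.6,spect,1,27,16,NA,18,12.50
sphere4,18.5MBq,19.6,spect,1,15,8,NA,14.72,84.00
cylinder1,37MBq,NA,spect,1,2,6716,NA,6180,-7.98
sphere1,37MBq,6,spect,1,46,55,NA,44.86,-18.44
sphere2,37MBq,17,spect,1,25,20.5,21.0,22.58,7.52
sphere3,37MBq,23.4,spect,1,23,16,NA,17.55,9.69
sphere4,37MBq,43.8,spect,1,31,8,NA,10.45,30.63
cylinder1,55.5MBq,NA,spect,1,1,6716,NA,6737,0.31
sphere1,55.5MBq,9.9,spect,1,44,55,NA,45.32,-17.60
sphere2,55.5MBq,29.6,spect,1,33,20.5,21.0,18.62,-11.33
sphere3,55.5MBq,38.6,spect,1,33,16,NA,17.32,8.25
sphere4,55.5MBq,73.1,spect,1,31,8,NA,14.37,79.63
cylinder1,74MBq,NA,spect,1,NA,6716,NA,NA,NA
sphere1,74MBq,16,spect,1,52,55,NA,33.72,-38.69
sphere2,74MBq,45,spect,1,21,20.5,21.0,23.5,11.90
sphere3,74MBq,57,spect,1,21,16,NA,18.05,12.81
sphere4,74MBq,114,spect,1,31,8,NA,5.95,-25.63
cylinder2,55MBq,NA,spect,1,46,774,NA,709,-8.40
cylinder2,116MBq,NA,spect,1,46,774,NA,667,-13.82
cylinder3,72MBq,NA,spect,1,33,473,NA,455,-3.81
cylinder1,18.5MBq,NA,spect_ct,1,2,6716,NA,6521,-2.90
sphere1,18.5MBq,2.8,spect_ct,1,48,55,NA,57.22,4.04
sphere2,18.5MBq,7.6,spect_ct,1,27,20.5,21.0,27.08,28.95
sphere3,18.5MBq,9.6,spect_ct,1,29,16,NA,16.94,5.88
sphere4,18.5MBq,19.6,spect_ct,1,19,8,NA,10.91,36.38
cylinder1,37MBq,NA,spect_ct,1,1,6716,NA,6735,0.28
sphere1,37MBq,6,spect_ct,1,42,55,NA,49.06,-10.80
sphere2,37MBq,17,spect_ct,1,29,20.5,21.0,20.52,-2.29
sphere3,37MBq,23.4,spect_ct,1,27,16,NA,14.95,-6.56
sphere4,37MBq,43.8,spect_ct,1,35,8,NA,9.08,13.50
cylinder1,55.5MBq,NA,spect_ct,1,1,6716,NA,6737,0.31
sphere1,55.5MBq,9.9,spect_ct,1,31,55,NA,59.28,7.78
sphere2,55.5MBq,29.6,spect_ct,1,31,20.5,21.0,19.3,-8.10
sphere3,55.5MBq,38.6,spect_ct,1,35,16,NA,16.17,1.06
sphere4,55.5MBq,73.1,spect_ct,1,40,8,NA,10.53,31.63
cylinder1,74MBq,NA,spect_ct,1,NA,6716,NA,NA,NA
sphere1,74MBq,16,spect_ct,1,31,55,NA,54.86,-0.25
sphere2,74MBq,45,spect_ct,1,27,20.5,21.0,19.81,-5.67
sphere3,74MBq,57,spect_ct,1,27,16,NA,15.49,-3.19
sphere4,74MBq,114,spect_ct,1,21,8,NA,8.32,4.00
cylinder2,55MBq,NA,spect_ct,1,25,774,NA,795,2.71
cylinder2,116MBq,NA,spect_ct,1,35,774,NA,770,-0.52
cylinder3,72MBq,NA,spect_ct,1,23,473,NA,515,8.88
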