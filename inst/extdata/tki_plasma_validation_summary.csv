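analyte,level,nominal_conc,bias_pct,rsd_r_pct,rsd_ip_pct,published_tol_lower_pct,published_tol_upper_pct
AFA,1,5,-0.24,5.60,5.65,-13.38,12.90
AFA,2,25,1.31,5.54,4.94,-9.96,12.58
AFA,3,75,0.63,2.70,2.63,-5.44,6.71
AFA,4,125,1.29,2.23,2.42,-4.52,7.09
AFA,5,175,0.56,1.87,1.66,-3.23,4.36
AFA,6,250,-0.25,1.63,1.91,-4.77,4.27
IBR,1,5,-1.21,5.83,5.22,-12.96,10.54
IBR,2,75,7.63,1.96,1.89,3.28,11.98
IBR,3,150,0.77,1.85,2.83,-7.94,9.48
IBR,4,250,-0.47,1.77,3.47,-12.89,11.95
IBR,5,350,0.43,2.02,3.48,-11.94,12.79
IBR,6,400,-0.07,1.87,2.25,-6.00,5.85
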