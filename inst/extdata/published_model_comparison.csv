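species,model,gint_mmol,AIC,dAIC_printed,R2,slope,slope_se,intercept,intercept_se
QF,BBD_MLD,5.5,-106.88,0,0.88,1.04,0.09,0.001,0.005
QF,BBD_n,7.1,-106.6,0.28,0.87,1.06,0.09,0.0006,0.005
QF,BBD_d,20.3,-102.32,4.56,0.84,1.23,0.13,-0.013,0.007
QF,BB,8.9,-102.3,4.58,0.85,1.02,0.09,-0.01,0.006
QF,BB_meas_gMLD,5.5,-104.3,2.58,0.86,0.99,0.09,0.002,0.005
QI,BBD_MLD,5.3,-98.52,1.64,0.97,1.2,0.05,-0.0001,0.003
QI,BBD_n,9.1,-96.22,3.94,0.97,1.2,0.05,-0.002,0.008
QI,BBD_d,58.2,-69.92,30.24,0.85,1.6,0.17,-0.067,0.01
QI,BB,16.8,-98.14,2.02,0.98,1.3,0.05,-0.018,0.004
QI,BB_meas_gMLD,5.3,-100.16,0,0.98,1.2,0.04,-0.001,0.003
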