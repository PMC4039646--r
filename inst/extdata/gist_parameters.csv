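name,base,se,min,max,family
incidence,1.053e-05,1.39e-06,5.2e-06,1.5e-05,gamma
p_resectable,0.8,0.05,0.5,0.9,beta
relapse_rate,0.0464,0.0025,0.029,0.186,gamma
imatinib_failure_rate,0.351,0.103,0.205,0.645,gamma
sunitinib_failure_rate,0.974,0.085,0.533,1.435,gamma
thirdline_exit_rate,0.904,0.1,0.439,1.066,gamma
background_mortality,0.0314,0.0023,0.0269,0.0359,gamma
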