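variable,group1,mean1,sd1,n1,group2,mean2,sd2,n2,t_printed,p_printed,known_discrepancy
Age,spd,20.08,1.04,25,nonspd,20.04,1.31,25,-0.12,0.91,FALSE
Education,spd,13.76,0.97,25,nonspd,12.84,0.85,25,-3.57,0.001,FALSE
IQ estimates,spd,126.61,10.65,25,nonspd,126.71,9.36,25,0.03,0.97,FALSE
SPQ_Cognitive perception,spd,17.88,5.39,25,nonspd,4.64,3.13,25,-10.62,0.001,FALSE
SPQ_Interpersonal,spd,12.44,4.18,25,nonspd,2.60,1.94,25,-10.67,0.001,FALSE
SPQ_Disorganization,spd,9.36,2.14,25,nonspd,1.84,2.04,25,-12.74,0.001,FALSE
SPQ_Total score,spd,40.84,6.61,25,nonspd,9.16,5.06,25,-19.03,0.001,FALSE
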