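compound,n_train_pos,n_train_neg,n_test_pos,n_test_neg,pretreatment,n_factors,ccr_cal,ccr_cv,ccr_test,sens_cv,sens_test,spec_cv,spec_test,prec_cv,prec_test,cv_fp,cv_fn,test_fp,test_fn
diacetylmorphine,97,3,21,4,savgol_2nd_derivative,9,98.99,98.99,96.00,100.00,100.00,66.67,75.00,98.98,95.45,1,0,1,0
acetaminophen,97,3,21,4,snv,2,100.00,98.99,96.00,100.00,95.45,66.67,100.00,98.98,100.00,1,0,0,1
acetylcodeine,97,3,20,5,snv,5,98.99,98.99,96.00,100.00,100.00,66.67,80.00,98.98,95.00,1,0,1,0
monoacetylmorphine,97,3,21,4,savgol_2nd_derivative,9,98.99,98.99,96.00,100.00,100.00,66.67,75.00,98.98,95.23,1,0,1,0
caffeine,97,3,22,3,savgol_2nd_derivative,8,100.00,98.99,96.00,100.00,95.45,66.67,100.00,98.98,100.00,1,0,0,1
codeine,24,73,5,20,autoscale,15,92.93,82.83,80.00,62.50,60.00,90.41,85.00,68.18,50.00,7,9,3,2
diacetamate,96,4,20,5,savgol_2nd_derivative,14,98.99,97.98,96.00,100.00,100.00,50.00,80.00,97.96,95.23,2,0,1,0
methacetin,6,94,4,21,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
morphine,94,6,21,4,snv,3,96.97,96.97,88.00,100.00,100.00,50.00,25.00,96.90,87.50,3,0,3,0
noscapine,97,3,20,5,snv,5,98.99,98.99,96.00,100.00,100.00,66.67,80.00,98.98,95.23,1,0,1,0
papaverine,95,5,19,6,autoscale,5,97.98,97.98,92.00,100.00,100.00,97.89,89.47,97.94,90.48,2,0,2,0
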