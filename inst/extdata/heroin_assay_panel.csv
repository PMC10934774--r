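sample_id,purity_percent,diacetylmorphine,acetaminophen,diacetamate,caffeine,codeine,morphine,acetylcodeine,monoacetylmorphine,papaverine,noscapine,methacetin
S1,0.00%,-,-,-,-,-,-,-,-,-,-,-
S2,1.01%,+,+,+,+,+,+,+,+,-,+,-
S3,13.90%,+,+,+,+,+,+,+,+,+,+,+
S4,17.44%,+,+,+,+,+,+,+,+,-,+,+
S5,14.19%,+,+,+,+,+,+,+,+,-,+,-
S6,12.78%,+,+,+,+,+,+,+,+,+,+,+
S7,10.80%,+,+,+,+,+,+,+,+,+,+,+
S8,19.32%,+,+,+,+,+,+,+,+,+,+,+
S9,9.56%,+,+,+,+,+,+,+,+,+,+,+
S10,0.00%,-,-,-,-,-,-,-,-,-,-,-
S11,0.00%,-,-,-,-,-,-,-,-,-,-,-
S12,12.09%,+,+,+,+,+,+,+,+,+,+,-
S13,11.90%,+,+,+,+,+,+,+,+,+,+,-
S14,9.92%,+,+,+,+,+,+,+,+,+,+,+
S15,10.08%,+,+,+,+,+,+,+,+,+,+,-
S16,10.48%,+,+,+,+,+,+,+,+,+,+,-
S17,10.28%,+,+,+,+,+,+,+,+,+,+,-
S18,9.63%,+,+,+,+,-,+,+,+,+,+,-
S19,11.86%,+,+,+,+,+,+,+,+,+,+,-
S20,12.40%,+,+,+,+,-,+,+,+,+,+,-
S21,22.72%,+,+,+,+,-,+,+,+,+,+,-
S22,12.02%,+,+,+,+,+,+,+,+,+,+,-
S23,11.04%,+,+,+,+,+,+,+,+,+,+,+
S24,8.98%,+,+,+,+,-,+,+,+,+,+,-
S25,10.22%,+,+,+,+,-,+,+,+,+,+,-
S26,9.98%,+,+,+,+,+,+,+,+,+,+,-
S27,10.04%,+,+,+,+,+,+,+,+,+,+,-
S28,15.05%,+,+,+,+,-,+,+,+,+,+,-
S29,16.74%,+,+,+,+,+,+,+,+,+,+,-
S30,11.84%,+,+,+,+,+,+,+,+,+,+,-
S31,9.99%,+,+,+,+,-,+,+,+,+,+,-
S32,12.29%,+,+,+,+,-,+,+,+,+,+,-
S33,56.53%,+,-,+,+,-,-,+,+,+,+,-
S34,9.60%,+,+,+,+,-,+,+,+,+,+,-
S35,10.43%,+,+,+,+,-,+,+,+,+,+,-
S36,17.55%,+,+,+,+,+,+,+,+,+,+,-
S37,17.22%,+,+,+,+,+,+,+,+,+,+,-
S38,9.51%,+,+,+,+,+,+,+,+,+,+,-
S39,14.44%,+,+,+,+,-,+,+,+,+,+,-
S40,14.32%,+,+,+,+,+,+,+,+,+,+,-
S41,17.17%,+,+,+,+,-,+,+,+,+,+,-
S42,13.76%,+,+,+,+,+,+,+,+,+,+,-
S43,10.01%,+,+,+,+,-,+,+,+,+,+,-
S44,12.00%,+,+,+,+,-,+,+,+,+,+,-
S45,13.76%,+,+,+,+,-,+,+,+,+,+,-
S46,9.76%,+,+,+,+,-,+,+,+,+,+,-
S47,9.89%,+,+,+,+,-,+,+,+,+,+,-
S48,0.21%,+,+,-,+,-,-,-,+,-,-,-
S49,36.61%,+,-,-,-,-,-,+,+,+,+,-
S50,17.37%,+,+,+,+,+,+,+,+,+,+,-
S51,17.77%,+,+,+,+,+,+,+,+,+,+,-
S52,13.19%,+,+,+,+,-,+,+,+,+,+,-
S53,9.17%,+,+,+,+,-,+,+,+,+,+,-
S54,6.16%,+,+,+,+,-,+,+,+,+,+,-
S55,9.29%,+,+,+,+,-,+,+,+,+,+,-
S56,10.41%,+,+,+,+,-,+,+,+,+,+,-
S57,20.23%,+,+,+,+,-,+,+,+,+,+,-
S58,35.69%,+,+,+,+,-,+,+,+,+,+,-
S59,14.95%,+,+,+,+,-,+,+,+,+,+,-
S60,10.06%,+,+,+,+,-,+,+,+,+,+,-
S61,18.76%,+,+,+,+,-,+,+,+,+,+,-
S62,10.49%,+,+,+,+,-,+,+,+,+,+,-
S63,10.71%,+,+,+,+,-,+,+,+,+,+,-
S64,13.72%,+,+,+,+,-,+,+,+,+,+,-
S65,10.08%,+,+,+,+,-,+,+,+,+,+,-
S66,10.16%,+,+,+,+,-,+,+,+,+,+,-
S67,10.16%,+,+,+,+,-,+,+,+,+,+,-
S68,10.20%,+,+,+,+,-,+,+,+,+,+,-
S69,0.42%,+,+,+,+,-,-,+,+,-,+,-
S70,9.96%,+,+,+,+,-,+,+,+,+,+,-
S71,5.31%,+,+,+,+,-,+,+,+,+,+,-
S72,10.97%,+,+,+,+,-,+,+,+,+,+,-
S73,7.61%,+,+,+,+,-,+,+,+,+,+,-
S74,9.50%,+,+,+,+,-,+,+,+,+,+,-
S75,18.35%,+,+,+,+,-,+,+,+,+,+,-
S76,8.18%,+,+,+,+,+,+,+,+,+,+,-
S77,10.97%,+,+,+,+,-,+,+,+,+,+,-
S78,10.82%,+,+,+,+,-,+,+,+,+,+,-
S79,10.91%,+,+,+,+,-,+,+,+,+,+,-
S80,10.71%,+,+,+,+,-,+,+,+,+,+,-
S81,17.74%,+,+,+,+,-,+,+,+,+,+,-
S82,17.61%,+,+,+,+,-,+,+,+,+,+,-
S83,0.00%,-,-,-,-,-,-,-,-,-,-,-
S84,12.01%,+,+,+,+,-,+,+,+,+,+,-
S85,12.16%,+,+,+,+,-,+,+,+,+,+,-
S86,9.85%,+,+,+,+,-,+,+,+,+,+,-
S87,9.03%,+,+,+,+,-,+,+,+,+,+,-
S88,0.00%,-,-,-,-,-,-,-,-,-,-,-
S89,12.33%,+,+,+,+,-,+,+,+,+,+,-
S90,7.13%,+,+,+,+,-,+,+,+,+,+,-
S91,17.55%,+,+,+,+,-,+,+,+,+,+,-
S92,1.82%,+,+,+,+,-,-,+,+,+,+,-
S93,4.93%,+,+,+,+,-,+,+,+,+,+,-
S94,11.84%,+,+,+,+,-,+,+,+,+,+,-
S95,11.62%,+,+,+,+,-,+,+,+,+,+,-
S96,11.43%,+,+,+,+,-,+,+,+,+,+,-
S97,6.66%,+,+,+,+,-,+,+,+,+,+,-
S98,10.16%,+,+,+,+,-,+,+,+,+,+,-
S99,14.31%,+,+,+,+,-,+,+,+,+,+,-
S100,22.35%,+,+,+,+,-,+,+,+,+,+,-
S101,11.31%,+,+,+,+,-,+,+,+,+,+,-
S102,4.92%,+,+,+,+,-,+,+,+,+,+,+
S103,4.30%,+,+,+,+,-,+,+,+,+,+,-
S104,12.45%,+,+,+,+,-,+,+,+,+,+,-
S105,11.34%,+,+,+,+,-,+,+,+,+,+,-
S106,47.78%,+,+,+,+,-,-,+,+,+,+,-
S107,10.16%,+,+,+,+,-,+,+,+,+,+,-
S108,10.02%,+,+,+,+,-,+,+,+,+,+,-
S109,14.41%,+,+,+,+,-,+,+,+,+,+,-
S110,14.20%,+,+,+,+,-,+,+,+,+,+,-
S111,13.01%,+,+,+,+,-,+,+,+,+,+,+
S112,20.96%,+,+,+,+,-,+,+,+,+,+,-
S113,44.67%,+,+,+,+,-,+,+,+,+,+,-
S114,0.00%,-,+,-,+,-,-,-,-,-,-,-
S115,0.00%,-,+,-,+,-,-,-,-,-,-,-
S116,19.68%,+,+,+,+,-,+,+,+,+,+,-
S117,1.97%,+,+,+,+,-,+,+,+,+,+,-
S118,5.74%,+,+,+,+,-,+,+,+,+,+,-
S119,9.60%,+,+,+,+,-,+,+,+,+,+,-
S120,8.81%,+,+,+,+,-,+,+,+,+,+,-
S121,23.67%,+,+,+,+,-,+,+,+,+,+,-
S122,10.52%,+,+,+,+,-,+,+,+,+,+,-
S123,14.21%,+,+,+,+,-,+,+,+,+,+,-
S124,14.22%,+,+,+,+,-,+,+,+,+,+,-
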