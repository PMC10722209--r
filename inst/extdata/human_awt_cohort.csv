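heart,atrium,driver,q25_mm,median_mm,mean_mm,q75_mm,std_mm,cavity_cm3,tissue_cm3
H1,LA,FALSE,3.48,4.40,5.30,6.72,2.56,34.99,33.73
H1,RA,TRUE,3.41,4.69,5.44,6.82,2.91,66.38,47.75
H2,LA,FALSE,3.40,4.50,4.51,5.80,1.65,32.27,23.66
H2,RA,TRUE,3.38,4.53,4.53,5.98,2.03,42.16,31.51
H3,LA,FALSE,2.84,3.87,3.91,3.87,1.47,39.60,24.99
H3,RA,TRUE,2.77,4.27,4.48,4.27,2.10,36.08,24.11
H4,LA,TRUE,2.90,3.92,4.33,5.60,1.98,39.16,27.73
H4,RA,TRUE,3.51,5.16,5.53,7.21,2.66,45.07,34.37
H5,LA,TRUE,2.66,3.62,3.62,4.73,1.50,34.58,25.68
H5,RA,FALSE,2.29,3.47,3.47,5.13,2.14,28.96,19.77
H6,LA,TRUE,3.24,4.38,4.70,5.66,2.14,32.27,24.56
H6,RA,FALSE,3.14,4.43,4.76,5.96,2.27,42.16,32.59
H7,LA,FALSE,2.87,3.83,3.83,4.98,1.66,47.10,27.56
H7,RA,FALSE,2.68,3.96,3.96,5.99,2.19,54.21,22.89
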