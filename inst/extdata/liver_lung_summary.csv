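organ,tumour,metric,mean,sd,sd_over_mean,min,max
liver,1,area_cm2,1.46,0.14,0.1,1.03,1.61
liver,2,area_cm2,11.66,2.96,0.25,8.46,18.62
liver,3,area_cm2,30.21,6.40,0.21,15.47,45.51
liver,4,area_cm2,4.88,0.37,0.08,3.92,5.78
liver,5,area_cm2,7.58,0.75,0.1,6.39,9.20
liver,6,area_cm2,22.32,4.11,0.18,14.55,27.01
liver,1,diameter_mm,17.66,0.94,0.05,15.23,19.02
liver,2,diameter_mm,46.02,4.06,0.09,40.28,57.06
liver,3,diameter_mm,76.72,10.14,0.13,51.83,105.49
liver,4,diameter_mm,27.22,1.03,0.04,24.68,29.21
liver,5,diameter_mm,35.71,2.61,0.07,31.79,41.74
liver,6,diameter_mm,61.77,7.67,0.12,50.97,77.78
lung,1,area_cm2,1.32,0.19,0.14,0.89,1.60
lung,2,area_cm2,0.31,0.04,0.13,0.21,0.36
lung,3,area_cm2,0.55,0.10,0.18,0.34,0.77
lung,4,area_cm2,4.87,0.43,0.09,4.06,5.75
lung,5,area_cm2,15.19,0.39,0.03,14.32,15.93
lung,6,area_cm2,2.60,0.26,0.1,1.99,2.96
lung,7,area_cm2,1.42,0.15,0.11,1.18,1.69
lung,1,diameter_mm,14.30,0.07,0,12.23,15.83
lung,2,diameter_mm,7.43,0.37,0.05,6.51,8.14
lung,3,diameter_mm,10.76,1.04,0.1,8.88,12.61
lung,4,diameter_mm,29.86,2.43,0.08,24.95,34.52
lung,5,diameter_mm,48.78,0.76,0.02,47.33,50.27
lung,6,diameter_mm,22.67,2.22,0.1,17.54,27.16
lung,7,diameter_mm,16.28,1.03,0.06,14.81,18.33
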