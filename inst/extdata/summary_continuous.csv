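cohort,variable,role,units,family,group,p1,p2,p3,floor,upper,note
nhanes,age,demographic,years,lognormal,pso,48,35,60.75,18,Inf,
nhanes,age,demographic,years,lognormal,psa,58,47,66,18,Inf,
nhanes,bmi,demographic,kg/m2,lognormal,pso,28.6,25.26,33.49,0.01,Inf,
nhanes,bmi,demographic,kg/m2,lognormal,psa,29.8,25.9,34.6,0.01,Inf,
nhanes,wbc_count,serum,10^9/L,lognormal,pso,7.3,5.9,8.7,0.01,Inf,
nhanes,wbc_count,serum,10^9/L,lognormal,psa,7.2,6.1,8.76,0.01,Inf,
nhanes,lymphocyte_pct,serum,%,lognormal,pso,27.5,23.02,33.1,0.01,100,
nhanes,lymphocyte_pct,serum,%,lognormal,psa,27.5,23.1,34,0.01,100,
nhanes,monocyte_pct,serum,%,lognormal,pso,7.8,6.5,9.1,0.01,100,
nhanes,monocyte_pct,serum,%,lognormal,psa,7.7,6.7,9.1,0.01,100,
nhanes,neutrophil_pct,serum,%,lognormal,pso,61.25,54.7,65.9,0.01,100,
nhanes,neutrophil_pct,serum,%,lognormal,psa,62,53.8,66.5,0.01,100,
nhanes,eosinophil_pct,serum,%,lognormal,pso,2.48,1.7,3.58,0.01,100,
nhanes,eosinophil_pct,serum,%,lognormal,psa,2.2,1.4,3,0.01,100,
nhanes,basophil_pct,serum,%,lognormal,pso,0.6,0.4,0.9,0.01,100,
nhanes,basophil_pct,serum,%,lognormal,psa,0.7,0.5,1,0.01,100,
nhanes,lymphocyte_count,serum,10^9/L,lognormal,pso,2,1.6,2.5,0.01,Inf,
nhanes,lymphocyte_count,serum,10^9/L,lognormal,psa,1.9,1.6,2.4,0.01,Inf,
nhanes,monocyte_count,serum,10^9/L,lognormal,pso,0.5,0.5,0.7,0.01,Inf,printed Q1 equals median
nhanes,monocyte_count,serum,10^9/L,lognormal,psa,0.59,0.4,0.7,0.01,Inf,
nhanes,neutrophil_count,serum,10^9/L,lognormal,pso,4.4,3.4,5.5,0.01,Inf,
nhanes,neutrophil_count,serum,10^9/L,lognormal,psa,4.4,3.3,5.58,0.01,Inf,
nhanes,eosinophil_count,serum,10^9/L,lognormal,pso,0.2,0.1,0.3,0.01,Inf,
nhanes,eosinophil_count,serum,10^9/L,lognormal,psa,0.2,0.1,0.2,0.01,Inf,printed Q3 equals median
nhanes,basophil_count,serum,10^9/L,lognormal,pso,0,0,0.1,0.01,Inf,printed median and Q1 are zero
nhanes,basophil_count,serum,10^9/L,lognormal,psa,0.02,0,0.1,0.01,Inf,printed Q1 is zero
nhanes,rbc_count,serum,10^12/L,normal,pso,4.65,0.5,,0.01,Inf,
nhanes,rbc_count,serum,10^12/L,normal,psa,4.68,0.47,,0.01,Inf,
nhanes,hemoglobin,serum,g/dL,lognormal,pso,14.2,13.1,15.2,0.01,Inf,
nhanes,hemoglobin,serum,g/dL,lognormal,psa,14.1,13,14.6,0.01,Inf,
nhanes,hematocrit,serum,%,normal,pso,41.57,4.38,,0.01,100,
nhanes,hematocrit,serum,%,normal,psa,41.33,3.78,,0.01,100,
nhanes,mcv,serum,fL,lognormal,pso,89.9,87.1,92.85,0.01,Inf,
nhanes,mcv,serum,fL,lognormal,psa,89.6,85.9,92.2,0.01,Inf,
nhanes,mch,serum,pg,lognormal,pso,30.7,29.33,31.7,0.01,Inf,
nhanes,mch,serum,pg,lognormal,psa,30.2,28.7,31.3,0.01,Inf,
nhanes,rdw,serum,fL,lognormal,pso,12.9,12.3,13.7,0.01,Inf,
nhanes,rdw,serum,fL,lognormal,psa,13.79,13.3,14.4,0.01,Inf,
nhanes,platelet_count,serum,10^9/L,lognormal,pso,239,204.25,284,0.01,Inf,
nhanes,platelet_count,serum,10^9/L,lognormal,psa,247.51,197,285,0.01,Inf,
nhanes,pdw,serum,fL,lognormal,pso,8.1,7.6,8.78,0.01,Inf,
nhanes,pdw,serum,fL,lognormal,psa,8.3,7.7,8.9,0.01,Inf,
nhanes,crp,serum,mg/dL,lognormal,pso,0.43,0.17,1.1,0.01,Inf,
nhanes,crp,serum,mg/dL,lognormal,psa,4.24,1.69,7.52,0.01,Inf,
nhanes,albumin,serum,g/dL,lognormal,pso,7.3,5.9,8.7,0.01,Inf,printed row duplicates the white-blood-cell row and contradicts the cross-cohort table albumin of about 4.2 g/dL; transcribed as printed
nhanes,albumin,serum,g/dL,lognormal,psa,7.2,6.1,8.76,0.01,Inf,printed row duplicates the white-blood-cell row and contradicts the cross-cohort table albumin of about 4.2 g/dL; transcribed as printed
chinese,age,demographic,years,normal,pso,46.84,13.89,,18,Inf,
chinese,age,demographic,years,normal,psa,49.24,15.06,,18,Inf,
chinese,bmi,demographic,kg/m2,lognormal,pso,24.92,22.28,27.68,0.01,Inf,
chinese,bmi,demographic,kg/m2,lognormal,psa,26.12,23.31,28.72,0.01,Inf,
chinese,bsa,comorbidity,%,lognormal,pso,7,5,8,0.01,100,
chinese,bsa,comorbidity,%,lognormal,psa,8,6,9,0.01,100,
chinese,wbc_count,serum,10^9/L,lognormal,pso,6.7,5.3,8.07,0.01,Inf,
chinese,wbc_count,serum,10^9/L,lognormal,psa,6.6,4.8,7.2,0.01,Inf,
chinese,lymphocyte_pct,serum,%,normal,pso,26.36,7.61,,0.01,100,
chinese,lymphocyte_pct,serum,%,normal,psa,32.09,9.61,,0.01,100,
chinese,monocyte_pct,serum,%,lognormal,pso,7.35,6.23,8.8,0.01,100,
chinese,monocyte_pct,serum,%,lognormal,psa,6.7,5.5,7.9,0.01,100,
chinese,neutrophil_pct,serum,%,normal,pso,62.68,8.38,,0.01,100,
chinese,neutrophil_pct,serum,%,normal,psa,58.07,10.96,,0.01,100,
chinese,eosinophil_pct,serum,%,lognormal,pso,2.1,1.2,3.2,0.01,100,
chinese,eosinophil_pct,serum,%,lognormal,psa,1.8,1.2,3,0.01,100,
chinese,basophil_pct,serum,%,lognormal,pso,0.5,0.4,0.7,0.01,100,
chinese,basophil_pct,serum,%,lognormal,psa,0.4,0.3,0.6,0.01,100,
chinese,lymphocyte_count,serum,10^9/L,lognormal,pso,1.6,1.3,2,0.01,Inf,
chinese,lymphocyte_count,serum,10^9/L,lognormal,psa,1.8,1.51,1.94,0.01,Inf,
chinese,monocyte_count,serum,10^9/L,lognormal,pso,0.5,0.4,0.6,0.01,Inf,
chinese,monocyte_count,serum,10^9/L,lognormal,psa,0.4,0.35,0.42,0.01,Inf,
chinese,neutrophil_count,serum,10^9/L,normal,pso,4.24,1.4,,0.01,Inf,
chinese,neutrophil_count,serum,10^9/L,normal,psa,3.48,1.26,,0.01,Inf,
chinese,eosinophil_count,serum,10^9/L,lognormal,pso,0.14,0.08,0.21,0.01,Inf,
chinese,eosinophil_count,serum,10^9/L,lognormal,psa,0.11,0.06,0.17,0.01,Inf,
chinese,basophil_count,serum,10^9/L,lognormal,pso,0.03,0.02,0.05,0.01,Inf,
chinese,basophil_count,serum,10^9/L,lognormal,psa,0.02,0.01,0.04,0.01,Inf,
chinese,rbc_count,serum,10^12/L,normal,pso,4.55,0.57,,0.01,Inf,
chinese,rbc_count,serum,10^12/L,normal,psa,4.33,0.65,,0.01,Inf,
chinese,hemoglobin,serum,g/dL,lognormal,pso,14,12.53,14.9,0.01,Inf,
chinese,hemoglobin,serum,g/dL,lognormal,psa,12.9,11.8,14.7,0.01,Inf,
chinese,hematocrit,serum,%,lognormal,pso,40.96,36.99,43.88,0.01,100,
chinese,hematocrit,serum,%,lognormal,psa,39.78,35.08,43.4,0.01,100,
chinese,mcv,serum,fL,lognormal,pso,90.1,86.23,92.45,0.01,Inf,
chinese,mcv,serum,fL,lognormal,psa,89.8,85.9,93.8,0.01,Inf,
chinese,mch,serum,pg,normal,pso,33.93,0.98,,0.01,Inf,
chinese,mch,serum,pg,normal,psa,33.4,1.25,,0.01,Inf,
chinese,rdw,serum,fL,lognormal,pso,13.2,12.83,13.7,0.01,Inf,
chinese,rdw,serum,fL,lognormal,psa,13.3,12.7,14,0.01,Inf,
chinese,platelet_count,serum,10^9/L,lognormal,pso,207,181.25,254.75,0.01,Inf,
chinese,platelet_count,serum,10^9/L,lognormal,psa,215,186,300,0.01,Inf,
chinese,pdw,serum,fL,lognormal,pso,8.85,8.3,9.57,0.01,Inf,
chinese,pdw,serum,fL,lognormal,psa,8.8,8.3,9.6,0.01,Inf,
chinese,crp,serum,mg/dL,lognormal,pso,1.38,1,3.77,0.01,Inf,
chinese,crp,serum,mg/dL,lognormal,psa,5.3,1,16.55,0.01,Inf,
chinese,albumin,serum,g/dL,lognormal,pso,4.02,3.78,4.31,0.01,Inf,
chinese,albumin,serum,g/dL,lognormal,psa,4.04,3.69,4.38,0.01,Inf,
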