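cohort,variable,role,group,category,code,count
nhanes,gender,demographic,pso,male,1,275
nhanes,gender,demographic,pso,female,0,299
nhanes,gender,demographic,psa,male,1,63
nhanes,gender,demographic,psa,female,0,82
nhanes,race,demographic,pso,Mexican American,1,48
nhanes,race,demographic,pso,Other Hispanic,2,47
nhanes,race,demographic,pso,Non-Hispanic White,3,342
nhanes,race,demographic,pso,Non-Hispanic Black,4,76
nhanes,race,demographic,pso,Other,5,61
nhanes,race,demographic,psa,Mexican American,1,10
nhanes,race,demographic,psa,Other Hispanic,2,11
nhanes,race,demographic,psa,Non-Hispanic White,3,75
nhanes,race,demographic,psa,Non-Hispanic Black,4,33
nhanes,race,demographic,psa,Other,5,16
nhanes,education,demographic,pso,Did not graduate from junior high school,1,35
nhanes,education,demographic,pso,Did not graduate high school,2,78
nhanes,education,demographic,pso,High school graduate,3,130
nhanes,education,demographic,pso,Some college,4,183
nhanes,education,demographic,pso,College graduate,5,148
nhanes,education,demographic,psa,Did not graduate from junior high school,1,9
nhanes,education,demographic,psa,Did not graduate high school,2,17
nhanes,education,demographic,psa,High school graduate,3,33
nhanes,education,demographic,psa,Some college,4,52
nhanes,education,demographic,psa,College graduate,5,34
nhanes,smoking,comorbidity,pso,yes,1,327
nhanes,smoking,comorbidity,pso,no,0,247
nhanes,smoking,comorbidity,psa,yes,1,80
nhanes,smoking,comorbidity,psa,no,0,65
nhanes,drinking,comorbidity,pso,yes,1,447
nhanes,drinking,comorbidity,pso,no,0,127
nhanes,drinking,comorbidity,psa,yes,1,124
nhanes,drinking,comorbidity,psa,no,0,21
nhanes,diabetes,comorbidity,pso,yes,1,100
nhanes,diabetes,comorbidity,pso,no,0,474
nhanes,diabetes,comorbidity,psa,yes,1,32
nhanes,diabetes,comorbidity,psa,no,0,113
nhanes,hypertension,comorbidity,pso,yes,1,234
nhanes,hypertension,comorbidity,pso,no,0,340
nhanes,hypertension,comorbidity,psa,yes,1,74
nhanes,hypertension,comorbidity,psa,no,0,71
nhanes,rash_range,comorbidity,pso,Little or no psoriasis,1,400
nhanes,rash_range,comorbidity,pso,Only a few patches,2,97
nhanes,rash_range,comorbidity,pso,Scattered patches,3,62
nhanes,rash_range,comorbidity,pso,Extensive psoriasis,4,15
nhanes,rash_range,comorbidity,psa,Little or no psoriasis,1,42
nhanes,rash_range,comorbidity,psa,Only a few patches,2,96
nhanes,rash_range,comorbidity,psa,Scattered patches,3,5
nhanes,rash_range,comorbidity,psa,Extensive psoriasis,4,2
chinese,gender,demographic,pso,male,1,48
chinese,gender,demographic,pso,female,0,50
chinese,gender,demographic,psa,male,1,18
chinese,gender,demographic,psa,female,0,19
chinese,race,demographic,pso,Other,5,98
chinese,race,demographic,psa,Other,5,37
chinese,diabetes,comorbidity,pso,yes,1,21
chinese,diabetes,comorbidity,pso,no,0,77
chinese,diabetes,comorbidity,psa,yes,1,16
chinese,diabetes,comorbidity,psa,no,0,21
chinese,hypertension,comorbidity,pso,yes,1,29
chinese,hypertension,comorbidity,pso,no,0,69
chinese,hypertension,comorbidity,psa,yes,1,20
chinese,hypertension,comorbidity,psa,no,0,17
chinese,rash_range,comorbidity,pso,Little or no psoriasis,1,8
chinese,rash_range,comorbidity,pso,Only a few patches,2,12
chinese,rash_range,comorbidity,pso,Scattered patches,3,60
chinese,rash_range,comorbidity,pso,Extensive psoriasis,4,18
chinese,rash_range,comorbidity,psa,Little or no psoriasis,1,1
chinese,rash_range,comorbidity,psa,Only a few patches,2,1
chinese,rash_range,comorbidity,psa,Scattered patches,3,28
chinese,rash_range,comorbidity,psa,Extensive psoriasis,4,7
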