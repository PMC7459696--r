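"node_id","sex","age","maternal_education","household_income","bmi","mvpa","group","bmi_category","meets_pa_guideline","participation","enjoying_time","do_pa","recreation_safety","healthy_experience"
"c01","M",11.9244106626138,"less_than_hs","low",15.8823417138726,50.8604906436186,"MARA_SMS","normal",0,1,1,1,0,1
"c02","F",10.2137065324932,"less_than_hs","low",16.5571837770224,30.9510225584451,"MARA_SMS","normal",0,1,1,1,1,0
"c03","M",11.8455044291914,"complete_hs","low",16.9657538395401,87.5833755973832,"MARA_SMS","normal",1,1,1,1,1,1
"c04","F",9.25221183616668,"complete_hs","middle",20.6455586522691,57.0848489219895,"MARA_SMS","normal",0,0,1,1,1,1
"c05","M",11.3853801907972,"less_than_hs","low_middle",23.6858804593813,56.7551743591011,"MARA_SMS","overweight",0,0,1,0,1,0
"c06","F",11.2029387904331,"complete_hs","low",20.6115455420804,61.2244349748988,"MARA_SMS","normal",1,1,1,1,0,1
"c07","F",10.9492362421006,"less_than_hs","low",15.4620583234039,94.0263020613668,"MARA_SMS","normal",1,1,1,0,1,1
"c08","F",10.7341698342934,"incomplete_hs","middle",16.737268893938,60.9672616803402,"MARA_SMS","normal",1,1,1,1,1,1
"c09","M",11.9844059208408,"university","low",14.0649191128285,61.8444611341649,"MARA_SMS","underweight",1,1,0,1,1,0
"c10","M",10.0339275486767,"incomplete_hs","low",16.4005943680086,31.7736453419327,"MARA_SMS","normal",0,1,1,0,1,1
"c11","M",10.2345687840134,"less_than_hs","low",14.5583288439285,94.1100303840429,"MARA_SMS","normal",1,1,1,1,1,1
"c12","M",11.0216343719512,"less_than_hs","low_middle",17.0360132955544,106.515121701129,"MARA_SMS","normal",1,1,0,1,1,1
"c13","F",10.5831602849066,"less_than_hs","low",20.1065120056646,31.2944343591503,"MARA_SMS","normal",0,1,1,1,1,1
"c14","M",10.7431098716334,"complete_hs","low",21.9678133717602,62.6379470021404,"MARA_SMS","overweight",1,1,1,1,1,1
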