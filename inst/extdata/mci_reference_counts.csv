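variable,level,type,n_no_event,n_event,mean_no_event,sd_no_event,mean_event,sd_event
group_size,,size,27771,5890,,,,
sex,Female,categorical,14654,3538,,,,
sex,Male,categorical,13117,2352,,,,
race_ethnicity,Hispanic,categorical,5065,1515,,,,
race_ethnicity,NHB,categorical,4328,776,,,,
race_ethnicity,NHW,categorical,12008,2577,,,,
race_ethnicity,Other,categorical,1266,200,,,,
race_ethnicity,Unknown,categorical,5104,822,,,,
age,,continuous,,,59.4,21.2,74.4,12.2
smoking,Current smoker,categorical,4007,569,,,,
smoking,Former smoker,categorical,4995,1103,,,,
smoking,Never smoker,categorical,3221,615,,,,
smoking,Unknown,categorical,15548,3603,,,,
bmi,,continuous,,,27.4,6.72,26.9,5.46
death,,binary,3749,1383,,,,
anxiety,,binary,9673,1895,,,,
apathy,,binary,32,6,,,,
depression,,binary,12163,2653,,,,
hypertension,,binary,17907,4588,,,,
diabetes,,binary,9115,2386,,,,
cerebrovascular_diseases,,binary,8088,2313,,,,
cardiovascular_diseases,,binary,22025,5103,,,,
atrial_fibrillation,,binary,3266,982,,,,
hypercholesterolemia,,binary,4214,1081,,,,
myocardial_infarction,,binary,2303,601,,,,
congestive_heart_failure,,binary,4559,1212,,,,
peripheral_vascular_disease,,binary,5280,1446,,,,
cerebrovascular_disease,,binary,6964,2047,,,,
chronic_pulmonary_disease,,binary,8540,1825,,,,
rheumatic_disease,,binary,1263,241,,,,
peptic_ulcer_disease,,binary,1060,234,,,,
mild_liver_disease,,binary,3348,503,,,,
diabetes_without_chronic_complication,,binary,8170,2131,,,,
diabetes_with_chronic_complication,,binary,3608,936,,,,
hemiplegia_or_paraplegia,,binary,2166,351,,,,
renal_disease,,binary,4363,1189,,,,
any_malignancy,,binary,3158,553,,,,
moderate_severe_liver_disease,,binary,513,64,,,,
metastatic_solid_tumor,,binary,750,81,,,,
aids_hiv,,binary,562,33,,,,
obesity,,binary,7961,1235,,,,
hyperlipidemia,,binary,12375,3134,,,,
stroke,,binary,13570,3376,,,,
traumatic_brain_injury,,binary,6088,1881,,,,
sleep_disorder,,binary,3153,583,,,,
periodontitis,,binary,6323,1177,,,,
alcohol_use_disorder,,binary,225,32,,,,
exercise,,binary,2554,383,,,,
visual_impairment,,binary,754,89,,,,
hearing_impairment,,binary,453,112,,,,
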