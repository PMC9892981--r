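sex,age_band,indicator,mean,sd
male,20-29,wc,84,8.5
male,20-29,sbp,118,12
male,20-29,dbp,74,9
male,20-29,fbs,92,14
male,20-29,tg,120,80
male,20-29,hdl,50,12
male,30-39,wc,85,8.5
male,30-39,sbp,120,12
male,30-39,dbp,76,9
male,30-39,fbs,95,14
male,30-39,tg,140,85
male,30-39,hdl,48,12
male,40-49,wc,86,8.5
male,40-49,sbp,122,12
male,40-49,dbp,78,9
male,40-49,fbs,98,15
male,40-49,tg,150,90
male,40-49,hdl,47,12
male,50-59,wc,87,8.5
male,50-59,sbp,125,13
male,50-59,dbp,79,9
male,50-59,fbs,101,16
male,50-59,tg,145,85
male,50-59,hdl,46,12
male,60-69,wc,87,9
male,60-69,sbp,128,14
male,60-69,dbp,78,9
male,60-69,fbs,104,17
male,60-69,tg,135,80
male,60-69,hdl,46,12
male,70+,wc,86,9
male,70+,sbp,131,15
male,70+,dbp,76,9
male,70+,fbs,106,18
male,70+,tg,125,70
male,70+,hdl,47,12
female,20-29,wc,74,8
female,20-29,sbp,110,11
female,20-29,dbp,70,8.5
female,20-29,fbs,88,12
female,20-29,tg,85,55
female,20-29,hdl,58,13
female,30-39,wc,76,8
female,30-39,sbp,112,11
female,30-39,dbp,72,8.5
female,30-39,fbs,90,12
female,30-39,tg,95,60
female,30-39,hdl,57,13
female,40-49,wc,78,8.5
female,40-49,sbp,116,12
female,40-49,dbp,74,9
female,40-49,fbs,93,13
female,40-49,tg,110,65
female,40-49,hdl,56,13
female,50-59,wc,81,8.5
female,50-59,sbp,121,13
female,50-59,dbp,76,9
female,50-59,fbs,97,14
female,50-59,tg,125,70
female,50-59,hdl,54,13
female,60-69,wc,83,9
female,60-69,sbp,126,14
female,60-69,dbp,77,9
female,60-69,fbs,101,15
female,60-69,tg,130,70
female,60-69,hdl,52,13
female,70+,wc,84,9
female,70+,sbp,130,15
female,70+,dbp,76,9
female,70+,fbs,104,16
female,70+,tg,125,65
female,70+,hdl,51,13
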