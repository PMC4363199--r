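patient_id,age,education,tmt_a,tmt_b,dst,wordlist_learning,wordlist_recall,pegboard_dom,pegboard_nondom,q_memory,q_slowed,q_attention,q_prospective,q_informant,q_interest,q_mood,diagnosis,efavirenz
P01,55,10,47.5,83.6,48,20.6,7.7,76.5,78,rarely,never,sometimes,rarely,rarely,not_at_all,not_at_all,ANI,TRUE
P02,47,11,35.5,102,55,22.6,8.6,68,68.7,sometimes,rarely,never,sometimes,never,several_days,not_at_all,ANI,TRUE
P03,61,11,40,82.2,28,21.7,4.8,75.8,91.5,never,sometimes,rarely,rarely,rarely,not_at_all,not_at_all,ANI,TRUE
P04,44,11,30.1,76,50,18.8,7.8,80,74.2,rarely,never,sometimes,sometimes,never,several_days,not_at_all,ANI,FALSE
P05,66,12,53,95.2,44,20,7.3,81.8,83.7,sometimes,rarely,never,rarely,rarely,not_at_all,more_than_half,ANI,FALSE
P06,49,12,34.6,102,45,23,8.8,67,67.6,never,sometimes,rarely,sometimes,never,several_days,not_at_all,ANI,FALSE
P07,53,12,34.9,68.2,33,23,5.2,68.8,82.8,rarely,never,sometimes,rarely,rarely,not_at_all,not_at_all,ANI,FALSE
P08,70,12,41.6,122.8,37,14.8,6,104.6,94.5,sometimes,rarely,never,sometimes,never,several_days,not_at_all,MND,TRUE
P09,45,12,44.5,68,54,22.3,8.4,69,69.8,never,sometimes,rarely,rarely,rarely,not_at_all,not_at_all,MND,FALSE
P10,64,13,41,136.8,37,21.4,6.2,77,78.5,rarely,never,sometimes,sometimes,never,several_days,not_at_all,MND,FALSE
P11,52,13,34,66,33,23.4,5.2,67.7,81.6,sometimes,rarely,never,rarely,rarely,not_at_all,not_at_all,MND,FALSE
P12,58,13,52,121,26,15,4.5,93,102,never,sometimes,rarely,sometimes,never,several_days,not_at_all,HAD,TRUE
P13,48,12,35.5,66,55,22.6,5.9,68,68.7,rarely,never,sometimes,rarely,rarely,not_at_all,not_at_all,ANI,TRUE
P14,67,12,40,82.2,38,21.7,6.4,92.6,91.5,sometimes,rarely,never,sometimes,never,several_days,not_at_all,ANI,FALSE
P15,42,12,30.1,76,50,24.8,7.8,62,74.2,never,sometimes,rarely,rarely,rarely,not_at_all,not_at_all,ANI,FALSE
P16,56,13,30.4,81.4,49,21,5.4,75.4,76.8,rarely,never,sometimes,sometimes,never,several_days,not_at_all,MND,FALSE
P17,51,13,47.5,74.8,41,22,8.2,72.1,73.2,often,rarely,never,rarely,rarely,not_at_all,not_at_all,ANI,TRUE
P18,64,13,39,136.8,39,22,6.6,74.6,90.2,always,sometimes,often,sometimes,never,several_days,more_than_half,ANI,FALSE
P19,46,14,29.2,74,37,21.2,5.8,61,73.1,often,never,sometimes,rarely,rarely,not_at_all,not_at_all,MND,FALSE
P20,69,11,33,92.6,45,16.8,7.4,93.8,82.4,always,rarely,often,sometimes,never,several_days,not_at_all,MND,FALSE
P21,47,13,33.7,62,46,23.4,5.9,66,66.5,often,sometimes,rarely,rarely,rarely,not_at_all,more_than_half,ANI,FALSE
P22,65,13,38,77,40,22.4,6.7,73.4,100.6,always,never,often,sometimes,never,several_days,not_at_all,ANI,FALSE
P23,41,12,28.3,72,52,21.6,8.2,71,72,often,rarely,never,rarely,rarely,not_at_all,not_at_all,ANI,FALSE
P24,54,13,38.5,77,51,21.6,5.4,73.2,74.4,always,sometimes,often,sometimes,never,several_days,not_at_all,ANI,FALSE
P25,72,14,46.4,100.4,33,19.7,5.4,83.6,100.5,often,never,sometimes,rarely,rarely,not_at_all,not_at_all,MND,FALSE
P26,50,12,47.5,88,46,23.8,7.3,66.6,80.4,always,rarely,often,sometimes,never,several_days,not_at_all,NORMAL,FALSE
P27,68,12,34,95.2,44,20,7.3,81.8,83.7,often,sometimes,rarely,rarely,rarely,not_at_all,not_at_all,NORMAL,FALSE
P28,43,13,34.6,64,45,23,8.8,67,67.6,always,never,often,sometimes,never,several_days,not_at_all,NORMAL,FALSE
P29,46,13,31.9,58,48,24,7.6,64,76.4,sometimes,rarely,never,rarely,rarely,not_at_all,not_at_all,NORMAL,TRUE
P30,52,12,32.2,85.8,47,20.2,7.5,65.5,79.2,never,sometimes,rarely,sometimes,never,several_days,not_at_all,NORMAL,FALSE
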