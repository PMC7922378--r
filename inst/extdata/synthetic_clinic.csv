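case_id,age,BMI,HbA1c,EAG,creatinine,cholesterol
pt01,77,28.7,9.4,13.3,100,4.2
pt02,79,26.5,,12.9,67,4.6
pt03,64,28.2,10.6,11.1,87,4.1
pt04,69,27.9,9.4,12.2,65,5.3
pt05,48,27.1,9.9,11.4,112,6
pt06,66,24.5,10.6,12.9,90,4.6
pt07,58,27,9,11.7,75,4.8
pt08,61,26.6,9.5,12.1,92,4.1
pt09,66,33.2,8.7,10.1,63,
pt10,70,32.3,9.1,10.4,103,5.4
pt11,62,32.4,9,11.6,,3.7
pt12,83,32,9.7,10.4,57,6.2
pt13,67,32.7,9.3,,79,4.1
pt14,60,32.7,8.3,11.7,93,4.2
pt15,66,29.4,9.3,11.3,80,3.8
pt16,61,34.9,8.3,11.2,69,4
pt17,53,29.9,6.4,7,98,4.7
pt18,66,29.3,7.7,8.6,116,5.4
pt19,70,27.9,,6.9,51,4.4
pt20,65,30,7.4,10.2,102,4.8
pt21,65,28.5,6.6,7.8,73,4.8
pt22,63,28.8,8.2,9.1,95,5.9
pt23,69,27.1,7.7,9.5,53,6.8
pt24,52,31.1,6.9,8.9,76,4.1
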