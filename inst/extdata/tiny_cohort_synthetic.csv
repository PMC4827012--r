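patient_id,visit,month,ohd2,ohd3,age_years,gender,site,smoker,bmi,activity,supplements,diabetes,egfr,crp
T01,baseline,1,2,47.3,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T02,baseline,1,2,57.3,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T03,baseline,2,2,47.3,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T04,baseline,2,2,57.3,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T05,baseline,3,2,49.3,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T06,baseline,3,2,59.3,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T07,baseline,4,2,52.9,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T08,baseline,4,2,62.9,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T09,baseline,5,2,57.1,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T10,baseline,5,2,67.1,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T11,baseline,6,2,60.7,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T12,baseline,6,2,70.7,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T13,baseline,7,2,62.7,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T14,baseline,7,2,72.7,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T15,baseline,8,2,62.7,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T16,baseline,8,2,72.7,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T17,baseline,9,2,60.7,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T18,baseline,9,2,70.7,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T19,baseline,10,2,57.1,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T20,baseline,10,2,67.1,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T21,baseline,11,2,52.9,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T22,baseline,11,2,62.9,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T23,baseline,12,2,49.3,55,male,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
T24,baseline,12,2,59.3,70,female,bergen,no,25,ge2h_per_week,never_seldom,no,90,2
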