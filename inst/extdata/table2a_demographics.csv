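variable,level,n_sample,benchmark_pct,unweighted_pct,unweighted_ci_lo,unweighted_ci_hi,diff_unweighted_pct,weighted_pct,weighted_ci_lo,weighted_ci_hi,diff_weighted_pct
age,18-24,4224,11.60,4.21,4.09,4.33,7.39,11.59,11.23,11.96,0.01
age,25-34,14239,17.70,14.18,13.97,14.40,3.52,17.68,17.34,18.03,0.02
age,35-44,13968,16.40,13.91,13.70,14.13,2.49,16.38,16.06,16.71,0.02
age,45-54,14964,15.80,14.91,14.69,15.13,0.89,15.78,15.48,16.09,0.02
age,55-64,21097,16.90,21.01,20.76,21.27,4.11,16.88,16.60,17.17,0.02
age,65+,31899,21.70,31.77,31.49,32.06,10.07,21.68,21.38,21.98,0.02
sex,Male,34520,48.40,34.39,34.09,34.68,14.01,48.40,47.97,48.83,0.00
sex,Female,65871,51.60,65.61,65.32,65.91,14.01,51.60,51.17,52.03,0.00
sexual_orientation,Straight,89766,96.10,89.42,89.22,89.61,6.68,87.34,87.02,87.64,8.76
sexual_orientation,Bisexual/Gay/Lesbian/Other,10625,3.90,10.58,10.39,10.78,6.68,12.66,12.36,12.98,8.76
race_ethnicity,Non-Hispanic White,78233,63.60,77.93,77.67,78.18,14.33,63.60,63.15,64.05,0.00
race_ethnicity,Non-Hispanic Black,7674,11.30,7.64,7.48,7.81,3.66,11.30,11.00,11.61,0.00
race_ethnicity,Non-Hispanic Asian,3393,5.90,3.38,3.27,3.49,2.52,5.90,5.67,6.14,0.00
race_ethnicity,Hispanic,8689,16.50,8.66,8.48,8.83,7.84,16.50,16.12,16.89,0.00
race_ethnicity,Other,2402,2.70,2.39,2.30,2.49,0.31,2.70,2.56,2.85,0.00
education,Did not graduate high school,1784,11.60,1.78,1.70,1.86,9.82,1.96,1.84,2.09,9.64
education,High school graduate,8214,28.10,8.18,8.01,8.35,19.92,8.77,8.52,9.04,19.33
education,Some college,23440,30.60,23.35,23.09,23.61,7.25,23.66,23.29,24.04,6.94
education,College graduate,66953,29.80,66.69,66.40,66.98,36.89,65.60,65.18,66.02,35.80
income,"Less than $25,000",14734,13.80,14.68,14.46,14.90,0.88,13.80,13.50,14.11,0.00
income,"$25,000 to less than $35,000",7310,8.80,7.28,7.12,7.44,1.52,8.80,8.54,9.07,0.00
income,"$35,000 to less than $50,000",10091,12.70,10.05,9.87,10.24,2.65,12.70,12.39,13.01,0.00
income,"$50,000 or more",68256,64.70,67.99,67.70,68.28,3.29,64.70,64.27,65.12,0.00
home_ownership,Own,65605,68.20,65.35,65.05,65.64,2.85,68.20,67.79,68.61,0.00
home_ownership,Rent,28611,29.60,28.50,28.22,28.78,1.10,29.60,29.20,30.00,0.00
home_ownership,Other living arrangement,6175,2.20,6.15,6.00,6.30,3.95,2.20,2.11,2.30,0.00
region,Northeast,29639,17.40,29.52,29.24,29.81,12.12,17.40,17.14,17.66,0.00
region,Midwest,27970,21.10,27.86,27.58,28.14,6.76,21.10,20.80,21.40,0.00
region,South,18139,37.70,18.07,17.83,18.31,19.63,37.70,37.25,38.16,0.00
region,West,24643,23.80,24.55,24.28,24.81,0.75,23.80,23.45,24.15,0.00
self_reported_health,Excellent,13809,24.40,13.76,13.54,13.97,10.64,14.22,13.92,14.53,10.18
self_reported_health,Very good,38798,34.70,38.65,38.35,38.95,3.95,38.65,38.23,39.07,3.95
self_reported_health,Good,31755,27.50,31.63,31.34,31.92,4.13,32.07,31.67,32.47,4.57
self_reported_health,Fair,13250,10.60,13.20,12.99,13.41,2.60,12.54,12.26,12.82,1.94
self_reported_health,Poor,2779,2.90,2.77,2.67,2.87,0.13,2.52,2.40,2.66,0.38
usual_place_of_care,"Doctor's office, clinic or health center",87330,79.40,86.99,86.78,87.20,7.59,83.86,83.51,84.20,4.46
usual_place_of_care,Urgent care or minute clinic,5566,6.90,5.54,5.40,5.69,1.36,6.68,6.45,6.92,0.22
usual_place_of_care,Hospital emergency room,1041,1.40,1.04,0.98,1.10,0.36,1.17,1.07,1.27,0.23
usual_place_of_care,Some other place,2247,2.60,2.24,2.15,2.33,0.36,2.43,2.29,2.57,0.17
usual_place_of_care,Don't have a usual place for care,4207,9.70,4.19,4.07,4.32,5.51,5.87,5.64,6.10,3.83
last_visit_interval,Less than 1 year,95174,83.30,94.80,94.66,94.94,11.50,92.78,92.52,93.02,9.48
last_visit_interval,1 year to less than 2 years,3655,9.20,3.64,3.53,3.76,5.56,4.81,4.61,5.01,4.39
last_visit_interval,More than 2 years,1562,7.50,1.56,1.48,1.63,5.94,2.42,2.27,2.58,5.08
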