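marker	low	high	low_M	high_M	low_F	high_F	class
HDL-C	39	NA	NA	NA	NA	NA	lipid
LDL-C	NA	99	NA	NA	NA	NA	lipid
Total cholesterol	100	200	NA	NA	NA	NA	lipid
Triglycerides	NA	149	NA	NA	NA	NA	lipid
Homocysteine	NA	15	NA	NA	NA	NA	other
Glucose	65	99	NA	NA	NA	NA	diabetes
HbA1c	4.8	5.6	NA	NA	NA	NA	diabetes
Insulin	2.6	24.9	NA	NA	NA	NA	diabetes
GGT	NA	NA	NA	65	NA	60	diabetes
Vitamin D	30	100	NA	NA	NA	NA	other
Ferritin	NA	NA	30	400	15	150	other
Omega 3 index	5.4	NA	NA	NA	NA	NA	other
MCV	79	97	NA	NA	NA	NA	other
Morning cortisol	3.7	9.5	NA	NA	NA	NA	other
Systolic	NA	120	NA	NA	NA	NA	blood_pressure
Diastolic	NA	80	NA	NA	NA	NA	blood_pressure
Waist circumference	NA	NA	NA	40	NA	35	other
BMI	18.5	25	NA	NA	NA	NA	other
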