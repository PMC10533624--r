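# direction: 3L_to_5L
dimension,source_level,target_level,probability
MO,1,1,0.88053688996645973
MO,2,1,0.00026386508273735414
MO,3,1,1.1151264946619768e-14
MO,1,2,0.1191677094038969
MO,2,2,0.10645077197359151
MO,3,2,1.3410558998661435e-08
MO,1,3,0.0002953872190732535
MO,2,3,0.78657072588734223
MO,3,3,0.0002953872190732535
MO,1,4,1.3410558998661435e-08
MO,2,4,0.10645077197359151
MO,3,4,0.1191677094038969
MO,1,5,1.1151264946619768e-14
MO,2,5,0.00026386508273735414
MO,3,5,0.88053688996645973
SC,1,1,0.88053688996645973
SC,2,1,0.00026386508273735414
SC,3,1,1.1151264946619768e-14
SC,1,2,0.1191677094038969
SC,2,2,0.10645077197359151
SC,3,2,1.3410558998661435e-08
SC,1,3,0.0002953872190732535
SC,2,3,0.78657072588734223
SC,3,3,0.0002953872190732535
SC,1,4,1.3410558998661435e-08
SC,2,4,0.10645077197359151
SC,3,4,0.1191677094038969
SC,1,5,1.1151264946619768e-14
SC,2,5,0.00026386508273735414
SC,3,5,0.88053688996645973
UA,1,1,0.88053688996645973
UA,2,1,0.00026386508273735414
UA,3,1,1.1151264946619768e-14
UA,1,2,0.1191677094038969
UA,2,2,0.10645077197359151
UA,3,2,1.3410558998661435e-08
UA,1,3,0.0002953872190732535
UA,2,3,0.78657072588734223
UA,3,3,0.0002953872190732535
UA,1,4,1.3410558998661435e-08
UA,2,4,0.10645077197359151
UA,3,4,0.1191677094038969
UA,1,5,1.1151264946619768e-14
UA,2,5,0.00026386508273735414
UA,3,5,0.88053688996645973
PD,1,1,0.88053688996645973
PD,2,1,0.00026386508273735414
PD,3,1,1.1151264946619768e-14
PD,1,2,0.1191677094038969
PD,2,2,0.10645077197359151
PD,3,2,1.3410558998661435e-08
PD,1,3,0.0002953872190732535
PD,2,3,0.78657072588734223
PD,3,3,0.0002953872190732535
PD,1,4,1.3410558998661435e-08
PD,2,4,0.10645077197359151
PD,3,4,0.1191677094038969
PD,1,5,1.1151264946619768e-14
PD,2,5,0.00026386508273735414
PD,3,5,0.88053688996645973
AD,1,1,0.88053688996645973
AD,2,1,0.00026386508273735414
AD,3,1,1.1151264946619768e-14
AD,1,2,0.1191677094038969
AD,2,2,0.10645077197359151
AD,3,2,1.3410558998661435e-08
AD,1,3,0.0002953872190732535
AD,2,3,0.78657072588734223
AD,3,3,0.0002953872190732535
AD,1,4,1.3410558998661435e-08
AD,2,4,0.10645077197359151
AD,3,4,0.1191677094038969
AD,1,5,1.1151264946619768e-14
AD,2,5,0.00026386508273735414
AD,3,5,0.88053688996645973
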