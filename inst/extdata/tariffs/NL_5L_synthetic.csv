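# country: 'NL'
# version: "5L"
# full_health_value: 1
# range_min: -0.501
# range_max: 1
# note: 'Synthetic stand-in for the NL EQ-5D-5L value set: only the anxiety/depression level-5 main-effect decrement (0.421) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.040000000000000001,0
MO,3,level_dummy,0.070000000000000007,0
MO,4,level_dummy,0.22,0
MO,5,level_dummy,0.31,0
SC,2,level_dummy,0.040000000000000001,0
SC,3,level_dummy,0.059999999999999998,0
SC,4,level_dummy,0.17000000000000001,0
SC,5,level_dummy,0.22,0
UA,2,level_dummy,0.029999999999999999,0
UA,3,level_dummy,0.059999999999999998,0
UA,4,level_dummy,0.14999999999999999,0
UA,5,level_dummy,0.17999999999999999,0
PD,2,level_dummy,0.059999999999999998,0
PD,3,level_dummy,0.089999999999999997,0
PD,4,level_dummy,0.29999999999999999,0
PD,5,level_dummy,0.37,0
AD,2,level_dummy,0.070000000000000007,0
AD,3,level_dummy,0.11,0
AD,4,level_dummy,0.28000000000000003,0
AD,5,level_dummy,0.42099999999999999,0
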