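# country: 'US'
# version: "3L"
# full_health_value: 1
# range_min: -0.30500000000000005
# range_max: 1
# note: 'Synthetic stand-in for the US EQ-5D-3L value set: only the mobility level-3 main-effect decrement (0.490) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.14499999999999999,0
MO,3,level_dummy,0.48999999999999999,0
SC,2,level_dummy,0.11,0
SC,3,level_dummy,0.19,0
UA,2,level_dummy,0.085000000000000006,0
UA,3,level_dummy,0.16500000000000001,0
PD,2,level_dummy,0.12,0
PD,3,level_dummy,0.26000000000000001,0
AD,2,level_dummy,0.095000000000000001,0
AD,3,level_dummy,0.20000000000000001,0
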