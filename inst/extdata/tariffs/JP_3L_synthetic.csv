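# country: 'JP'
# version: "3L"
# full_health_value: 1
# range_min: -0.12099999999999991
# range_max: 1
# note: 'Synthetic stand-in for the JP EQ-5D-3L value set: only the mobility level-3 main-effect decrement (0.418) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.074999999999999997,0
MO,3,level_dummy,0.41799999999999998,0
SC,2,level_dummy,0.053999999999999999,0
SC,3,level_dummy,0.10199999999999999,0
UA,2,level_dummy,0.043999999999999997,0
UA,3,level_dummy,0.13300000000000001,0
PD,2,level_dummy,0.080000000000000002,0
PD,3,level_dummy,0.19400000000000001,0
AD,2,level_dummy,0.063,0
AD,3,level_dummy,0.112,0
,2,any_level_ge,0.14799999999999999,0
,3,any_level_ge,0.014,0
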