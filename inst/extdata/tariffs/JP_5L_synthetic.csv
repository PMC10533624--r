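# country: 'JP'
# version: "5L"
# full_health_value: 1
# range_min: -0.01999999999999999
# range_max: 1
# note: 'Synthetic stand-in for the JP EQ-5D-5L value set: only the anxiety/depression level-5 main-effect decrement (0.197) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.058999999999999997,0
MO,3,level_dummy,0.11,0
MO,4,level_dummy,0.17999999999999999,0
MO,5,level_dummy,0.24299999999999999,0
SC,2,level_dummy,0.051999999999999998,0
SC,3,level_dummy,0.099000000000000005,0
SC,4,level_dummy,0.16500000000000001,0
SC,5,level_dummy,0.224,0
UA,2,level_dummy,0.043999999999999997,0
UA,3,level_dummy,0.085000000000000006,0
UA,4,level_dummy,0.14099999999999999,0
UA,5,level_dummy,0.189,0
PD,2,level_dummy,0.039,0
PD,3,level_dummy,0.074999999999999997,0
PD,4,level_dummy,0.124,0
PD,5,level_dummy,0.16700000000000001,0
AD,2,level_dummy,0.045999999999999999,0
AD,3,level_dummy,0.088999999999999996,0
AD,4,level_dummy,0.14799999999999999,0
AD,5,level_dummy,0.19700000000000001,0
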