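# country: 'US'
# version: "5L"
# full_health_value: 1
# range_min: -0.59200000000000008
# range_max: 1
# note: 'Synthetic stand-in for the US EQ-5D-5L value set: only the anxiety/depression level-5 main-effect decrement (0.340) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.096000000000000002,0
MO,3,level_dummy,0.122,0
MO,4,level_dummy,0.23699999999999999,0
MO,5,level_dummy,0.32200000000000001,0
SC,2,level_dummy,0.088999999999999996,0
SC,3,level_dummy,0.107,0
SC,4,level_dummy,0.22,0
SC,5,level_dummy,0.26100000000000001,0
UA,2,level_dummy,0.068000000000000005,0
UA,3,level_dummy,0.10100000000000001,0
UA,4,level_dummy,0.23000000000000001,0
UA,5,level_dummy,0.255,0
PD,2,level_dummy,0.059999999999999998,0
PD,3,level_dummy,0.098000000000000004,0
PD,4,level_dummy,0.318,0
PD,5,level_dummy,0.41399999999999998,0
AD,2,level_dummy,0.057000000000000002,0
AD,3,level_dummy,0.123,0
AD,4,level_dummy,0.29899999999999999,0
AD,5,level_dummy,0.34000000000000002,0
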