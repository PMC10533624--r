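# country: 'NL'
# version: "3L"
# full_health_value: 1
# range_min: -0.32900000000000013
# range_max: 1
# note: 'Synthetic stand-in for the NL EQ-5D-3L value set: only the mobility level-3 main-effect decrement (0.161) is the published anchor; all other coefficients are plausible synthetic values, NOT the published table.'
dimension,level,indicator,coefficient,offset
MO,2,level_dummy,0.035999999999999997,0
MO,3,level_dummy,0.161,0
SC,2,level_dummy,0.082000000000000003,0
SC,3,level_dummy,0.152,0
UA,2,level_dummy,0.032000000000000001,0
UA,3,level_dummy,0.057000000000000002,0
PD,2,level_dummy,0.085999999999999993,0
PD,3,level_dummy,0.32900000000000001,0
AD,2,level_dummy,0.124,0
AD,3,level_dummy,0.32500000000000001,0
,2,any_level_ge,0.070999999999999994,0
,3,any_level_ge,0.23400000000000001,0
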