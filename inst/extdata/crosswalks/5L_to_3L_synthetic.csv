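# direction: 5L_to_3L
dimension,source_level,target_level,probability
MO,1,1,0.88053690177496158
MO,2,1,0.49546264257784312
MO,3,1,0.10650697891920076
MO,4,1,0.0090747148443137467
MO,5,1,0.00029538722303456454
MO,1,2,0.11916771100200385
MO,2,2,0.49546264257784312
MO,3,2,0.78698604216159851
MO,4,2,0.49546264257784312
MO,5,2,0.11916771100200385
MO,1,3,0.00029538722303456454
MO,2,3,0.0090747148443137467
MO,3,3,0.10650697891920076
MO,4,3,0.49546264257784312
MO,5,3,0.88053690177496158
SC,1,1,0.88053690177496158
SC,2,1,0.49546264257784312
SC,3,1,0.10650697891920076
SC,4,1,0.0090747148443137467
SC,5,1,0.00029538722303456454
SC,1,2,0.11916771100200385
SC,2,2,0.49546264257784312
SC,3,2,0.78698604216159851
SC,4,2,0.49546264257784312
SC,5,2,0.11916771100200385
SC,1,3,0.00029538722303456454
SC,2,3,0.0090747148443137467
SC,3,3,0.10650697891920076
SC,4,3,0.49546264257784312
SC,5,3,0.88053690177496158
UA,1,1,0.88053690177496158
UA,2,1,0.49546264257784312
UA,3,1,0.10650697891920076
UA,4,1,0.0090747148443137467
UA,5,1,0.00029538722303456454
UA,1,2,0.11916771100200385
UA,2,2,0.49546264257784312
UA,3,2,0.78698604216159851
UA,4,2,0.49546264257784312
UA,5,2,0.11916771100200385
UA,1,3,0.00029538722303456454
UA,2,3,0.0090747148443137467
UA,3,3,0.10650697891920076
UA,4,3,0.49546264257784312
UA,5,3,0.88053690177496158
PD,1,1,0.88053690177496158
PD,2,1,0.49546264257784312
PD,3,1,0.10650697891920076
PD,4,1,0.0090747148443137467
PD,5,1,0.00029538722303456454
PD,1,2,0.11916771100200385
PD,2,2,0.49546264257784312
PD,3,2,0.78698604216159851
PD,4,2,0.49546264257784312
PD,5,2,0.11916771100200385
PD,1,3,0.00029538722303456454
PD,2,3,0.0090747148443137467
PD,3,3,0.10650697891920076
PD,4,3,0.49546264257784312
PD,5,3,0.88053690177496158
AD,1,1,0.88053690177496158
AD,2,1,0.49546264257784312
AD,3,1,0.10650697891920076
AD,4,1,0.0090747148443137467
AD,5,1,0.00029538722303456454
AD,1,2,0.11916771100200385
AD,2,2,0.49546264257784312
AD,3,2,0.78698604216159851
AD,4,2,0.49546264257784312
AD,5,2,0.11916771100200385
AD,1,3,0.00029538722303456454
AD,2,3,0.0090747148443137467
AD,3,3,0.10650697891920076
AD,4,3,0.49546264257784312
AD,5,3,0.88053690177496158
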