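"id","name","contract","capacity","home_base"
"kelly","Kelly","full_time",1,"hospital_1"
"james","James","full_time",1,"hospital_3"
"olivia","Olivia","full_time",1,"hospital_2"
"amelia","Amelia","full_time",1,"hospital_3"
"joseph","Joseph","full_time",1,"hospital_1"
"emily","Emily","full_time",1,"hospital_2"
"matthew","Matthew","full_time",1,"hospital_2"
"laura","Laura","full_time",1,"hospital_1"
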