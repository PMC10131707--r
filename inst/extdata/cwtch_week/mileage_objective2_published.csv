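"name","2019-10-14","2019-10-15","2019-10-16","2019-10-17","2019-10-18","2019-10-19","2019-10-20","Total"
"kelly",0,0,0,0,0,0,0,0
"james",0,0,0,0,0,0,0,0
"olivia",0,0,0,0,0,0,30,30
"amelia",0,17,0,0,0,0,0,17
"joseph",0,0,0,0,0,0,0,0
"emily",0,0,0,0,0,0,0,0
"matthew",0,0,0,0,0,0,0,0
"laura",0,0,0,0,0,0,0,0
"Total",0,17,0,0,0,0,30,47
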