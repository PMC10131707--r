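"name","2019-10-14","2019-10-15","2019-10-16","2019-10-17","2019-10-18","2019-10-19","2019-10-20"
"Kelly","Hospital 1","Hospital 3","AA","OFF","OFF","Hospital 1","Hospital 2"
"James","OFF","Hospital 2","OFF","Hospital 2","AA","AA","OFF"
"Olivia","Hospital 3","OFF","OFF","OFF","Hospital 2","Hospital 3","Hospital 1"
"Amelia","Hospital 2","AA","AA","OFF","OFF","OFF","OFF"
"Joseph","OFF","Hospital 1","Hospital 3","AA","AA","OFF","OFF"
"Emily","AA","OFF","Hospital 1","Hospital 3","Hospital 1","OFF","OFF"
"Matthew","OFF","OFF","Hospital 2","Hospital 1","Hospital 3","Hospital 2","Hospital 3"
"Laura","OFF","OFF","OFF","AA","OFF","OFF","AA"
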