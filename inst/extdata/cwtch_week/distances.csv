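"name","hospital_1","hospital_2","hospital_3"
"Kelly",0,20,30
"James",44,25,0
"Olivia",20,0,30
"Amelia",28,17,0
"Joseph",0,21,38
"Emily",32,0,18
"Matthew",29,0,35
"Laura",0,24,36
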