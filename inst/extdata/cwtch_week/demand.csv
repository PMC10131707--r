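"location","date","demand"
"hospital_1","2019-10-14",1
"hospital_2","2019-10-14",1
"hospital_3","2019-10-14",1
"aa","2019-10-14",1
"hospital_1","2019-10-15",1
"hospital_2","2019-10-15",1
"hospital_3","2019-10-15",1
"aa","2019-10-15",1
"hospital_1","2019-10-16",1
"hospital_2","2019-10-16",1
"hospital_3","2019-10-16",1
"aa","2019-10-16",2
"hospital_1","2019-10-17",1
"hospital_2","2019-10-17",1
"hospital_3","2019-10-17",1
"aa","2019-10-17",2
"hospital_1","2019-10-18",1
"hospital_2","2019-10-18",1
"hospital_3","2019-10-18",1
"aa","2019-10-18",2
"hospital_1","2019-10-19",1
"hospital_2","2019-10-19",1
"hospital_3","2019-10-19",1
"aa","2019-10-19",1
"hospital_1","2019-10-20",1
"hospital_2","2019-10-20",1
"hospital_3","2019-10-20",1
"aa","2019-10-20",1
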