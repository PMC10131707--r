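"id","name","kind"
"hospital_1","Hospital 1","hospital"
"hospital_2","Hospital 2","hospital"
"hospital_3","Hospital 3","hospital"
"aa","AA","telehealth_hub"
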