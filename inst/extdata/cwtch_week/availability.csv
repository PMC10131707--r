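"staff","date","status"
"kelly","2019-10-14","available"
"james","2019-10-14","available"
"olivia","2019-10-14","available"
"amelia","2019-10-14","available"
"joseph","2019-10-14","available"
"emily","2019-10-14","available"
"matthew","2019-10-14","available"
"laura","2019-10-14","available"
"kelly","2019-10-15","available"
"james","2019-10-15","available"
"olivia","2019-10-15","available"
"amelia","2019-10-15","available"
"joseph","2019-10-15","available"
"emily","2019-10-15","available"
"matthew","2019-10-15","available"
"laura","2019-10-15","available"
"kelly","2019-10-16","available"
"james","2019-10-16","available"
"olivia","2019-10-16","available"
"amelia","2019-10-16","available"
"joseph","2019-10-16","available"
"emily","2019-10-16","available"
"matthew","2019-10-16","available"
"laura","2019-10-16","available"
"kelly","2019-10-17","available"
"james","2019-10-17","available"
"olivia","2019-10-17","available"
"amelia","2019-10-17","available"
"joseph","2019-10-17","available"
"emily","2019-10-17","available"
"matthew","2019-10-17","available"
"laura","2019-10-17","available"
"kelly","2019-10-18","available"
"james","2019-10-18","available"
"olivia","2019-10-18","available"
"amelia","2019-10-18","available"
"joseph","2019-10-18","available"
"emily","2019-10-18","available"
"matthew","2019-10-18","available"
"laura","2019-10-18","available"
"kelly","2019-10-19","available"
"james","2019-10-19","available"
"olivia","2019-10-19","available"
"amelia","2019-10-19","available"
"joseph","2019-10-19","available"
"emily","2019-10-19","available"
"matthew","2019-10-19","available"
"laura","2019-10-19","available"
"kelly","2019-10-20","available"
"james","2019-10-20","available"
"olivia","2019-10-20","available"
"amelia","2019-10-20","available"
"joseph","2019-10-20","available"
"emily","2019-10-20","available"
"matthew","2019-10-20","available"
"laura","2019-10-20","available"
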