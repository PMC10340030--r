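# Reference young replacement sire: enters production in the first age bin,
# arrived at the stud at 6 months, net merit just below the elite decile,
# average sperm production (no deviation).
bull_id: replacement
start_age_bin: 1
arrival_age: 6
nm_bin: 9
pdev: 0
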