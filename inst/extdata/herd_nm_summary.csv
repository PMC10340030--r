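nm_bin,nm_low,nm_high,n_bulls,mean_pdev_pct,sd_pdev_pct,mean_bullval,sd_bullval
1,-151,152,8,4.2,31.7,-257759,21280
2,205,286,3,-29.9,26.9,-235546,38630
3,298,351,4,-3.5,33.7,-40291,120230
4,361,418,9,5.0,32.5,7151,103780
5,423,474,15,-0.3,26.8,210924,142140
6,479,559,40,1.7,29.3,168307,147720
7,560,636,55,-3.0,21.0,30979,83700
8,637,692,76,-6.9,22.4,64302,93650
9,693,756,87,4.8,28.8,3953,94440
10,757,950,99,3.6,41.6,-151324,71390
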