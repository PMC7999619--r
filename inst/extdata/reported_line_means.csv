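line_id,diet,profit,gwp,ap,ep,lo,fattening_feed_cost_eur,carcass_kg,lmp_pct
LRFI,reference,11.10,2.07,36.8,1.16,4.30,53.7,95.9,60.7
HRFI,reference,8.50,2.21,40.0,1.24,4.58,55.9,95.9,58.5
LRFI,lc,17.75,2.02,33.07,1.39,4.35,46.4,95.9,59.6
HRFI,lc,14.47,2.09,37.1,1.56,3.97,48.0,95.9,57.7
LRFI,least_score,16.28,1.96,35.6,1.27,3.53,48.2,96.0,60.0
HRFI,least_score,12.73,2.00,36.5,1.39,4.17,50.0,95.9,57.8
LRFI,joint,16.86,1.96,34.6,1.36,3.89,47.6,95.9,60.0
HRFI,joint,15.58,2.02,35.3,1.40,4.22,47.8,95.9,58.0
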