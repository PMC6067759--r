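county_id,state,year,rate_white,rate_black
Craighead,AR,2003,4.2,10.5
Craighead,AR,2013,5.6,3.9
Black Hawk,IA,2003,5.0,17.8
Black Hawk,IA,2013,4.9,7.5
Delaware,IN,2003,7.7,13.7
Delaware,IN,2013,9.7,12.4
Stearns,MN,2003,7.8,11.2
Stearns,MN,2013,7.2,9.5
National,,2003,7.0,13.4
National,,2013,7.0,12.8
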