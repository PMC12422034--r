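country,measure,integrated,standard,difference
Uganda,total,1412010798,1640535510,-228524712
Uganda,pct_gdp,1.20,1.40,-0.20
Uganda,pct_che,32.60,37.90,-5.30
Tanzania,total,1550251004,1622297064,-72046061
Tanzania,pct_gdp,0.89,0.93,-0.04
Tanzania,pct_che,23.13,24.20,-1.07
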