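"tissue","level","E","sigma_y","Et","nu","rho"
"skin","min",2,0.5,0.02,0.43,1000
"skin","avg",6,2.5,0.03,0.44,1100
"skin","max",15,4,0.04,0.45,1200
"flesh","min",0.5,0.05,0.002,0.43,1000
"flesh","avg",2,1,0.003,0.44,1100
"flesh","max",4,1.8,0.004,0.45,1200
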