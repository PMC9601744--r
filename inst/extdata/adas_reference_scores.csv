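item,ig_raw,ig_norm,cst_raw,cst_norm,relieff_raw,relieff_norm,avg_score
WORDRECALL,0.135,1.000,1956.268,1.000,0.144,0.683,0.894
COMMAND,0.049,0.246,699.447,0.242,0.026,0.100,0.196
CONSTRUCT,0.032,0.093,475.613,0.107,0.030,0.121,0.107
DELAYWORD,0.084,0.551,1327.623,0.621,0.208,1.000,0.724
NAMING,0.032,0.101,472.299,0.105,0.022,0.080,0.095
IDEATIONAL,0.038,0.150,534.736,0.143,0.015,0.047,0.113
ORIENT,0.044,0.201,691.697,0.237,0.081,0.372,0.270
WORDRECOG,0.062,0.364,975.468,0.408,0.172,0.826,0.533
RMBRTESTINSTR,0.021,0.002,298.131,0.000,0.005,0.000,0.001
LANGUAGE,0.028,0.059,389.760,0.055,0.009,0.016,0.043
WORDFIND,0.042,0.182,629.659,0.200,0.035,0.147,0.176
SPOKENLG,0.025,0.033,347.811,0.030,0.009,0.020,0.028
NUMBERCANCEL,0.021,0.000,314.056,0.010,0.060,0.268,0.092
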