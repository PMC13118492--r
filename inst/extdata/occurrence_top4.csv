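analyte,p_detect,cmin,cmean,cmax
flonicamid,0.362,0.013,0.048,0.382
propamocarb,0.275,0.015,0.056,1.030
acetamiprid,0.133,0.015,0.040,0.331
azoxystrobin,0.112,0.011,0.038,0.447
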