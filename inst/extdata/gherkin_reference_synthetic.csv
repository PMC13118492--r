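analyte,class,authorised,mrl_mg_kg,adi_mg_kg_bw_day,arfd_mg_kg_bw,loq_mg_kg
flonicamid,insecticide,TRUE,0.7,0.025,0.025,0.01
propamocarb,fungicide,TRUE,5,0.29,1,0.01
acetamiprid,insecticide,TRUE,0.5,0.025,0.025,0.01
azoxystrobin,fungicide,TRUE,1,0.2,,0.01
metalaxyl,fungicide,TRUE,0.01,0.08,0.5,0.01
chlorpyrifos,insecticide,FALSE,0.01,,,0.01
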