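# doputil example incubation data (hand-written fixture)
# units: chl ug/L; din dip tdp dop uM; apa nM P/h; time_d days
station_id,season,treatment,replicate,time_d,variable,value,censored
F1,summer,control,1,0,chl,1,FALSE
F1,summer,control,1,1,chl,2,FALSE
F1,summer,control,1,2,chl,3,FALSE
F1,summer,control,1,3,chl,4,FALSE
F1,summer,control,1,4,chl,5,FALSE
F1,summer,control,1,0,din,5,FALSE
F1,summer,control,1,1,din,4,FALSE
F1,summer,control,1,2,din,3,FALSE
F1,summer,control,1,3,din,2,FALSE
F1,summer,control,1,4,din,1,FALSE
F1,summer,control,1,0,dip,0.10,FALSE
F1,summer,control,1,1,dip,0.08,FALSE
F1,summer,control,1,2,dip,0.06,FALSE
F1,summer,control,1,3,dip,0.04,FALSE
F1,summer,control,1,4,dip,0.02,FALSE
F1,summer,control,1,0,apa,1,FALSE
F1,summer,control,1,2,apa,2,FALSE
F1,summer,control,1,4,apa,3,FALSE
F1,summer,control,1,0,dop,0.2,FALSE
F1,summer,control,1,4,dop,0.1,FALSE
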