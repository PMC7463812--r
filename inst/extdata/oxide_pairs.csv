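oxide,parent
co2,co
no2,no
picolinic_acid_noxide,picolinic_acid
cyanopyridine_4_noxide,cyanopyridine_4
pno,pyridine
cyanopyridine_3_noxide,cyanopyridine_3
tmao,tma
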