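substrate,oxidant,method,dH_r
pyridine,H2O2,B3LYP/6-31G*,-24.2
pyridine,H2O2,"M06/6-311G+(d,p)",-31.6
pyridine,DMDO,B3LYP/6-31G*,-30.6
pyridine,DMDO,"M06/6-311G+(d,p)",-39.7
tma,H2O2,B3LYP/6-31G*,-10.7
tma,H2O2,"M06/6-311G+(d,p)",-21.6
tma,DMDO,B3LYP/6-31G*,-17.1
tma,DMDO,"M06/6-311G+(d,p)",-29.7
quinuclidine,H2O2,B3LYP/6-31G*,-14.9
quinuclidine,H2O2,"M06/6-311G+(d,p)",-25.8
quinuclidine,DMDO,B3LYP/6-31G*,-21.3
quinuclidine,DMDO,"M06/6-311G+(d,p)",-33.9
manxine,H2O2,B3LYP/6-31G*,-8.4
manxine,H2O2,"M06/6-311G+(d,p)",-17.3
manxine,DMDO,B3LYP/6-31G*,-14.8
manxine,DMDO,"M06/6-311G+(d,p)",-25.4
quinuclidinone,H2O2,B3LYP/6-31G*,-9.8
quinuclidinone,H2O2,"M06/6-311G+(d,p)",-19.7
quinuclidinone,DMDO,B3LYP/6-31G*,-16.2
quinuclidinone,DMDO,"M06/6-311G+(d,p)",-27.8
azaadamantanone,H2O2,B3LYP/6-31G*,-10.9
azaadamantanone,H2O2,"M06/6-311G+(d,p)",-20.4
azaadamantanone,DMDO,B3LYP/6-31G*,-17.3
azaadamantanone,DMDO,"M06/6-311G+(d,p)",-28.5
manxinone,H2O2,B3LYP/6-31G*,8.0
manxinone,H2O2,"M06/6-311G+(d,p)",-1.5
manxinone,DMDO,B3LYP/6-31G*,1.6
manxinone,DMDO,"M06/6-311G+(d,p)",-9.6
azabicyclo331nonanone,H2O2,B3LYP/6-31G*,0.7
azabicyclo331nonanone,H2O2,"M06/6-311G+(d,p)",-8.9
azabicyclo331nonanone,DMDO,B3LYP/6-31G*,-5.7
azabicyclo331nonanone,DMDO,"M06/6-311G+(d,p)",-17.0
nmp,H2O2,B3LYP/6-31G*,3.3
nmp,H2O2,"M06/6-311G+(d,p)",-5.9
nmp,DMDO,B3LYP/6-31G*,-3.1
nmp,DMDO,"M06/6-311G+(d,p)",-14.0
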