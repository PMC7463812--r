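species_id,method,bde,neg_ttrs
co2,experimental,127.3,67.7
no2,experimental,73.5,13.9
picolinic_acid_noxide,experimental,65.9,6.3
cyanopyridine_4_noxide,experimental,63.5,3.9
pno,experimental,63.4,3.8
cyanopyridine_3_noxide,experimental,60.8,1.2
tmao,experimental,61.1,1.5
co2,B3LYP/6-31G*,129.5,67.8
no2,B3LYP/6-31G*,75.9,14.2
azacyclohexadiene_noxide,B3LYP/6-31G*,69.2,7.5
azacyclohexene_noxide,B3LYP/6-31G*,65.9,4.2
picolinic_acid_noxide,B3LYP/6-31G*,64.3,2.6
cyanopyridine_4_noxide,B3LYP/6-31G*,63.1,1.4
pno,B3LYP/6-31G*,62.1,0.4
cyanopyridine_3_noxide,B3LYP/6-31G*,59.7,-2.0
quinuclidine_noxide,B3LYP/6-31G*,52.8,-8.9
azaadamantanone_noxide,B3LYP/6-31G*,48.8,-12.9
tmao,B3LYP/6-31G*,48.6,-13.1
azabicyclo332decane_noxide,B3LYP/6-31G*,48.2,-13.5
quinuclidinone_noxide,B3LYP/6-31G*,47.7,-14.1
manxine_noxide,B3LYP/6-31G*,46.3,-15.4
azabicyclo433dodecane_noxide,B3LYP/6-31G*,39.3,-22.4
azabicyclo331nonanone_noxide,B3LYP/6-31G*,37.2,-24.6
nmp_noxide,B3LYP/6-31G*,34.6,-27.1
manxinone_noxide,B3LYP/6-31G*,29.9,-31.8
co2,"M06/6-311G+(d,p)",134.9,77.8
no2,"M06/6-311G+(d,p)",76.0,18.9
azacyclohexadiene_noxide,"M06/6-311G+(d,p)",68.7,11.6
azacyclohexene_noxide,"M06/6-311G+(d,p)",66.0,8.9
picolinic_acid_noxide,"M06/6-311G+(d,p)",62.0,4.9
cyanopyridine_4_noxide,"M06/6-311G+(d,p)",62.1,5.0
pno,"M06/6-311G+(d,p)",61.5,4.4
cyanopyridine_3_noxide,"M06/6-311G+(d,p)",58.9,1.8
quinuclidine_noxide,"M06/6-311G+(d,p)",55.7,-1.4
azaadamantanone_noxide,"M06/6-311G+(d,p)",50.3,-6.8
tmao,"M06/6-311G+(d,p)",51.5,-5.6
azabicyclo332decane_noxide,"M06/6-311G+(d,p)",50.2,-6.9
quinuclidinone_noxide,"M06/6-311G+(d,p)",49.6,-7.5
manxine_noxide,"M06/6-311G+(d,p)",47.2,-9.9
azabicyclo433dodecane_noxide,"M06/6-311G+(d,p)",40.4,-16.7
azabicyclo331nonanone_noxide,"M06/6-311G+(d,p)",38.8,-28.3
nmp_noxide,"M06/6-311G+(d,p)",35.8,-21.3
manxinone_noxide,"M06/6-311G+(d,p)",31.4,-25.7
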