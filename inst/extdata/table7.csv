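scheme,method,dh1,dh2,dh3,total
pyridine,experimental,2.7,-26.8,-20.8,-44.9
pyridine,B3LYP/6-31G*,7.2,-26.9,-18.3,-38.0
pyridine,"M06/6-311G+(d,p)",3.5,-29.0,-23.1,-48.6
benzene,experimental,5.7,-26.6,-28.3,-49.2
benzene,B3LYP/6-31G*,9.2,-26.9,-28.6,-46.3
benzene,"M06/6-311G+(d,p)",5.2,-28.9,-30.6,-54.3
pno,B3LYP/6-31G*,0.1,-23.6,-3.5,-27.0
pno,"M06/6-311G+(d,p)",3.6,-26.4,-8.2,-31.0
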