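method,dE_r,dH_r,bde_pno,bde_tmao
B3LYP/6-31G*,-13.2,-13.5,62.1,48.6
B3LYP/6-31G**,-13.2,-13.5,62.2,48.7
"M06/6-311G+(d,p)",-9.7,-10.0,61.5,51.5
B3PW91/6-31G*,-14.3,-14.7,63.8,49.1
B3PW91/6-31G**,-14.4,-14.6,63.9,49.3
"B3PW91/6-311G+(d,p)",-11.1,-11.8,62.7,50.9
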