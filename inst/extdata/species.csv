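id,name,formula,charge,unpaired_electrons
o_atom_3p,oxygen atom (3P),O,0,2
o2,dioxygen (triplet),O2,0,2
h2,dihydrogen,H2,0,0
h2o,water,H2O,0,0
h2o2,hydrogen peroxide,H2O2,0,0
co,carbon monoxide,CO,0,0
co2,carbon dioxide,CO2,0,0
no,nitric oxide,NO,0,1
no2,nitrogen dioxide,NO2,0,1
tma,trimethylamine,C3H9N,0,0
tmao,trimethylamine N-oxide,C3H9NO,0,0
pyridine,pyridine,C5H5N,0,0
pno,pyridine N-oxide,C5H5NO,0,0
nitromethane,nitromethane,CH3NO2,0,0
methyl_nitrite,methyl nitrite,CH3NO2,0,0
dimethylaminomethanol,N;N-dimethylaminomethanol,C3H9NO,0,0
hydroxypyridine_2,2-hydroxypyridine,C5H5NO,0,0
pyridone_2,2-pyridone,C5H5NO,0,0
benzene,benzene,C6H6,0,0
cyclohexadiene_13,1;3-cyclohexadiene,C6H8,0,0
cyclohexene,cyclohexene,C6H10,0,0
cyclohexane,cyclohexane,C6H12,0,0
azacyclohexadiene,1-aza-1;3-cyclohexadiene,C5H7N,0,0
azacyclohexene,1-azacyclohexene,C5H9N,0,0
piperidine,piperidine,C5H11N,0,0
azacyclohexadiene_noxide,1-aza-1;3-cyclohexadiene N-oxide,C5H7NO,0,0
azacyclohexene_noxide,1-azacyclohexene N-oxide,C5H9NO,0,0
piperidine_noxide,piperidine N-oxide,C5H11NO,0,0
phenol,phenol,C6H6O,0,0
cyclohexanol,cyclohexanol,C6H12O,0,0
phenoxide,phenoxide anion,C6H5O,-1,0
cyclohexanoxide,cyclohexanoxide anion,C6H11O,-1,0
t_butanol,t-butanol,C4H10O,0,0
t_butoxide,t-butoxide anion,C4H9O,-1,0
stilbene,(E)-stilbene (diphenyl analogue of benzene),C14H12,0,0
benzylideneaniline,N-benzylideneaniline (diphenyl analogue of pyridine),C13H11N,0,0
diphenylnitrone,alpha;N-diphenylnitrone (diphenyl analogue of PNO),C13H11NO,0,0
dmdo,dimethyldioxirane,C3H6O2,0,0
acetone,acetone,C3H6O,0,0
picolinic_acid,2-carboxylpyridine,C6H5NO2,0,0
picolinic_acid_noxide,2-carboxylpyridine N-oxide,C6H5NO3,0,0
cyanopyridine_4,4-cyanopyridine,C6H4N2,0,0
cyanopyridine_4_noxide,4-cyanopyridine N-oxide,C6H4N2O,0,0
cyanopyridine_3,3-cyanopyridine,C6H4N2,0,0
cyanopyridine_3_noxide,3-cyanopyridine N-oxide,C6H4N2O,0,0
quinuclidine,1-azabicyclo[2.2.2]octane (quinuclidine),C7H13N,0,0
quinuclidine_noxide,quinuclidine N-oxide,C7H13NO,0,0
manxine,1-azabicyclo[3.3.3]undecane (manxine),C10H19N,0,0
manxine_noxide,manxine N-oxide,C10H19NO,0,0
azabicyclo332decane,1-azabicyclo[3.3.2]decane,C9H17N,0,0
azabicyclo332decane_noxide,1-azabicyclo[3.3.2]decane N-oxide,C9H17NO,0,0
azabicyclo433dodecane,1-azabicyclo[4.3.3]dodecane,C11H21N,0,0
azabicyclo433dodecane_noxide,1-azabicyclo[4.3.3]dodecane N-oxide,C11H21NO,0,0
azaadamantanone,1-azaadamantan-2-one,C9H13NO,0,0
azaadamantanone_noxide,1-azaadamantan-2-one N-oxide,C9H13NO2,0,0
quinuclidinone,2-quinuclidinone,C7H11NO,0,0
quinuclidinone_noxide,2-quinuclidinone N-oxide,C7H11NO2,0,0
manxinone,2-manxinone,C10H17NO,0,0
manxinone_noxide,2-manxinone N-oxide,C10H17NO2,0,0
azabicyclo331nonanone,1-azabicyclo[3.3.1]nonan-2-one,C8H13NO,0,0
azabicyclo331nonanone_noxide,1-azabicyclo[3.3.1]nonan-2-one N-oxide,C8H13NO2,0,0
nmp,N-methyl-2-pyrrolidinone,C5H9NO,0,0
nmp_noxide,N-methyl-2-pyrrolidinone N-oxide,C5H9NO2,0,0
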