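# Named reaction schemes over the packaged registry.
# Coefficients are integers or "p/q" strings (exact rationals).
- id: eq_oat
  class: isodesmic
  reactants: {tmao: 1, pyridine: 1}
  products: {tma: 1, pno: 1}
- id: bde_tmao
  class: plain
  reactants: {tmao: 1}
  products: {tma: 1, o_atom_3p: 1}
- id: bde_pno
  class: plain
  reactants: {pno: 1}
  products: {pyridine: 1, o_atom_3p: 1}
- id: ttrs_tmao
  class: plain
  reactants: {tmao: 1}
  products: {tma: 1, o2: "1/2"}
- id: ttrs_pno
  class: plain
  reactants: {pno: 1}
  products: {pyridine: 1, o2: "1/2"}
- id: re_benzene
  class: isodesmic
  reactants: {cyclohexene: 3}
  products: {cyclohexane: 2, benzene: 1}
# Literature variant with the miscounted arene coefficient; it does not
# element-balance and is kept only to document the misprint.
- id: re_benzene_printed
  class: plain
  reactants: {cyclohexene: 3}
  products: {cyclohexane: 2, benzene: 2}
- id: re_pyridine
  class: isodesmic
  reactants: {cyclohexene: 2, azacyclohexene: 1}
  products: {cyclohexane: 2, pyridine: 1}
- id: re_pno
  class: isodesmic
  reactants: {cyclohexene: 2, azacyclohexene_noxide: 1}
  products: {cyclohexane: 2, pno: 1}
- id: ox_pyridine_h2o2
  class: plain
  reactants: {pyridine: 1, h2o2: 1}
  products: {pno: 1, h2o: 1}
- id: ox_pyridine_dmdo
  class: plain
  reactants: {pyridine: 1, dmdo: 1}
  products: {pno: 1, acetone: 1}
- id: ox_tma_h2o2
  class: plain
  reactants: {tma: 1, h2o2: 1}
  products: {tmao: 1, h2o: 1}
- id: ox_tma_dmdo
  class: plain
  reactants: {tma: 1, dmdo: 1}
  products: {tmao: 1, acetone: 1}
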