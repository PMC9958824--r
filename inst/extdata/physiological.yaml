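# Physiological ion table of brain tissue (mM), extracellular volume
# fraction 0.25, temperature 310 K. "A" are the impermeant anions
# (negatively charged metabolites and macromolecules); both sides are
# electro-neutral and total 304 mM.
alpha: 0.25
temperature: 310
ions:
  - {name: Na,   valence: 1,  permeant: true,  conc_out: 148, conc_in: 12}
  - {name: K,    valence: 1,  permeant: true,  conc_out: 4,   conc_in: 140}
  - {name: Cl,   valence: -1, permeant: true,  conc_out: 113, conc_in: 8}
  - {name: HCO3, valence: -1, permeant: true,  conc_out: 29,  conc_in: 10}
  - {name: A,    valence: -1, permeant: false, conc_out: 10,  conc_in: 134}
format: csv
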