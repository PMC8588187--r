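# Atom Property Correlation Table: 13C shift-range rules assigning carbon
# hybridization and hetero-neighbor constraints.  Rules are intersected when
# intervals overlap; intervals are [lo, hi) except the last, which is closed.
# hetero: fb = hetero neighbor forbidden, ob = obligatory, undefined = no claim.
# Editable: users may point apply_apct()/build_mcd() at their own copy.
rules:
  - {lo: 0,   hi: 20,  hyb: [sp3],      hetero: fb}
  - {lo: 20,  hi: 50,  hyb: [sp3],      hetero: undefined}
  - {lo: 50,  hi: 60,  hyb: [sp3],      hetero: ob}
  - {lo: 60,  hi: 90,  hyb: [sp3, sp],  hetero: undefined}
  - {lo: 90,  hi: 100, hyb: [sp3, sp2], hetero: undefined}
  - {lo: 100, hi: 165, hyb: [sp2],      hetero: undefined}
  - {lo: 165, hi: 190, hyb: [sp2],      hetero: ob}
  - {lo: 190, hi: 240, hyb: [sp2],      hetero: ob}
# Multiplicity-specific refinements (applied on top of the range rules):
mult_rules:
  - {lo: 0, hi: 60, mult: CH3, hyb: [sp3], hetero: undefined}
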