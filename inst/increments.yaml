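# Additive 13C shift increments: base value per carbon class plus
# alpha/beta/gamma substituent increments, in the style of the classic
# Grant-Paul/Pretsch additive schemes.  Values are rounded textbook-flavored
# defaults; the table is config and may be replaced by the user.
sp3:
  base: -2.3              # methane
  alpha_C: 9.1
  beta_C: 9.4
  gamma_C: -2.5
  alpha_O: 41.0
  beta_O: 8.0
  gamma_O: -5.0
  alpha_N: 26.0
  beta_N: 7.0
  gamma_N: -4.0
  alpha_sp2: 1.5          # extra for each unsaturated alpha carbon (benzylic)
sp2:
  base: 123.0             # vinylic / aromatic CH reference
  alpha_C: 9.0
  beta_C: 1.0
  alpha_O: 25.0           # enol ether / phenol-type ipso
  beta_O: -10.0
  alpha_N: 18.0
  beta_N: -8.0
carbonyl:
  ketone: 197.0           # C=O with C/H substituents only
  acyl_X: 170.0           # C=O additionally bound to O or N (ester, amide, acid)
  beta_C: 1.0
sp:
  base: 75.0
  alpha_C: 8.0
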