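# Published NRTL-SAC parameter estimates for the six organic compounds of the
# Adavosertib (AZD1775) manufacturing route: conceptual segment numbers
# (x = X hydrophilic, y_minus = Y- polar attractive, y_plus = Y+ polar
# repulsive, z = Z hydrophobic), enthalpy of fusion [kJ/mol], melting
# temperature [K] (null where the melting point was measured by DSC rather
# than estimated from solubility data), and the reported fit metrics.
# rmsle_excluding_flagged is the bracketed value excluding the degrading
# n-BuOAc measurements of compound 3.
solute_1:
  name: AZD1775 pyrimidine
  x: 0.000
  y_minus: 0.000
  y_plus: 0.000
  z: 3.477
  dh_fus: 34.920
  t_mp: 405.40
  sse: 5.461e-7
  rmsle: 3.067
solute_2:
  name: AZD1775 bromopyridine HBr
  x: 0.000
  y_minus: 0.101
  y_plus: 0.000
  z: 2.757
  dh_fus: 12.393
  t_mp: 442.21
  sse: 6.466e-6
  rmsle: 4.206
solute_3:
  name: AZD1775 hydroxymethylsulfanyl
  x: 0.488
  y_minus: 0.076
  y_plus: 0.000
  z: 0.000
  dh_fus: 43.151
  t_mp: null
  sse: 1.704e-4
  rmsle: 6.245
  rmsle_excluding_flagged: 0.096
solute_4:
  name: AZD1775 nitropip
  x: 0.761
  y_minus: 0.000
  y_plus: 0.000
  z: 0.000
  dh_fus: 29.249
  t_mp: null
  sse: 6.538e-4
  rmsle: 0.417
solute_5:
  name: AZD1775 aniline maleate
  x: 0.000
  y_minus: 0.076
  y_plus: 0.336
  z: 0.439
  dh_fus: 59.461
  t_mp: null
  sse: 8.027e-6
  rmsle: 0.858
solute_6:
  name: AZD1775 adavosertib maleate
  x: 0.000
  y_minus: 0.000
  y_plus: 0.856
  z: 2.620
  dh_fus: 64.810
  t_mp: null
  sse: 9.652e-9
  rmsle: 4.447
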