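# Solvent segment-parameter library — TEMPLATE, must be populated before use.
#
# The package does not ship segment numbers for real solvents: published
# NRTL-SAC solvent parameters (e.g. for acetonitrile, isopropyl alcohol,
# n-butyl acetate, toluene) are tabulated in the original model literature
# and should be copied here by the user. Loading this template as-is fails
# validation on purpose (values are absent).
#
# Per-solvent keys: x (X hydrophilic), y_minus (Y- polar attractive),
# y_plus (Y+ polar repulsive), z (Z hydrophobic); omitted keys default to 0.
MeCN:
  y_minus:
  y_plus:
  z:
IPA:
  x:
  z:
n-BuOAc:
  x:
  y_minus:
  z:
PhMe:
  z:
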