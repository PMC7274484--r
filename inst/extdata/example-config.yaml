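# Example rbcshape configuration: dimple-dominated pulling on a
# tensionless membrane (forces in pN/um^2, tension in pN/um).
membrane:
  kappa: 9
  lambda0: 0
  A_total: 135
force:
  F_dimple: 3.4
  F_rim: 0.28
  phi: 90
  t_star: 0.45
  w: 0.05
  coord: normalized
solver:
  mesh_n: 161
  mode: anchored-equator
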