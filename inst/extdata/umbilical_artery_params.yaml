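# Model parameters fixed for all simulations of the murine umbilical artery.
# Lengths in micrometers, stresses in kPa, angles in degrees from the axis.
geometry:
  A: 161.77        # unloaded inner radius
  B: 206.86        # unloaded inner/outer interface radius
  C: 236.92        # unloaded outer radius
  lambda_z: 1.28   # loaded (in vivo) axial stretch
inner:
  mu: 3.0          # GAG/matrix shear modulus, inner layer
  contractile: false
outer:
  mu: 0.1          # matrix shear modulus, outer layer
  contractile: true
  fibers:
    - {c1: 0.013, c2: 11.65, eta: 0.0}     # axial family
    - {c1: 2.66,  c2: 1.20,  eta: 90.0}    # circumferential family
    - {c1: 3.04,  c2: 4.23,  eta: 41.92}   # diagonal family
    - {c1: 3.04,  c2: 4.23,  eta: -41.92}  # diagonal family
tone:
  lambda_m: 2.5    # maximum contractile stretch
  lambda_0: 0.2    # minimum contractile stretch
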