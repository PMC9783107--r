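# Default particle-sticking parameter profile: silicon-like inhaler wall,
# polymeric drug microparticle, dry van der Waals contact, ambient air.
material:
  Es: 4.1e+9        # surface Young's modulus, Pa
  Ep: 1.0e+9        # particle Young's modulus, Pa
  nu_s: 0.35       # surface Poisson ratio
  nu_p: 0.40       # particle Poisson ratio
  WA: 0.039        # work of adhesion, J/m^2 (silicon-silicon, dry)
  ks: 0.5          # static friction coefficient
  f: 1.7           # near-wall drag correction factor
  Cu: 1.0          # Cunningham correction (spherical particles)
  rho_p: 1230.0    # particle density, kg/m^3
fluid:
  rho: 1.225       # air density at 1013.25 hPa, 15 C, kg/m^3
  mu: 1.7894e-05    # dynamic viscosity of air, Pa s
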