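# Baseline configuration of the ciliary-epithelium transport model.
# Units: SI except where noted. Transporter intensities are in units of
# 1e-6 mol/m^2/s and channel permeabilities in 1e-8 m/s (the conventional
# scalings); load_config() converts them to plain SI.

geometry:
  L: 1.0e-5        # cell layer thickness, m
  H: 6.0e-3        # posterior chamber length, m
  A_mem: 6.0e-4    # stromal and PC membrane area, m^2
  A_tj: 6.0e-7     # tight junction area, m^2
  A_pc: 2.6e-5     # PC cross-section, m^2

hydraulic:         # m/s/Pa
  K_s: 2.0e-11
  K_tj: 2.0e-11
  K_p: 2.0e-10

gas_permeability:  # m/s
  P_co2_s: 1.5e-3
  P_co2_tj: 1.5e-3
  P_co2_p: 1.5e-2
  P_h2co3_s: 1.28e-5
  P_h2co3_tj: 1.28e-5
  P_h2co3_p: 1.28e-4

reactions:
  k_d: 4.96e+5     # H2CO3 -> CO2 + H2O, 1/s
  k_h: 1.45e+3     # CO2 + H2O -> H2CO3, 1/s
  K_eq: 5.3        # HCO3- + H+ <-> H2CO3 association constant, 1/mM

other:
  T: 310           # K
  sigma: 1         # reflection coefficient
  z_X: -1.5        # valence of intracellular fixed charge

transporters:      # intensities, 1e-6 mol/m^2/s
  P_pump: 6
  P_nkcc: 1
  P_aes: 4
  P_aep: 0.4
  P_nbcp: 1.423    # calibrated, see vignette
  P_nbcs: 0.5901   # calibrated, see vignette
  P_nhe: 3.4

channels:          # permeabilities, 1e-8 m/s
  P_K_s: 5
  P_K_p: 30
  P_Cl_p: 6
  P_tj: 600

pump_kinetics:     # Na+-K+ ATPase Michaelis constants, mM
  pump_K_Na0: 0.2071
  pump_K_Na_slope: 8.33
  pump_K_K0: 0.1156
  pump_K_K_slope: 18.5

stroma:            # imposed boundary condition; mM, pH; V = 0 reference
  Na: 150
  K: 5
  Cl: 130
  HCO3: 25
  pH: 7.42

solver:
  tol: 1.0e-10
  max_iter: 60
  multistart: 20
  seed: 1234
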