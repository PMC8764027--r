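# Frozen default parameters of the cross-feeding serial-transfer simulator.
# None of these rate constants are measured values of the study system; they
# were calibrated once so that the model reproduces the qualitative behaviour
# of an obligate amino-acid cross-feeding coculture and its supplemented
# monoculture controls (see the package vignette, section "Calibration"),
# and are frozen here. All direction-of-effect checks run from this file.
r:            # maximum specific growth rate, 1/h
  TRP: 0.45
  TYR: 0.45
K_aa: 2       # Monod constant of the required amino acid, uM
rho: 16       # amino acid released per 1e9 new partner-feeding cells/ml, uM
rho_leak: 0.5 # basal leakage, uM per h per 1e9 cells/ml
              # (scaled in the model by antibiotic suppression)
q_aa: 5       # amino acid consumed per 1e9 new auxotroph cells/ml, uM
C: 1.0e+9     # carrying capacity, cells/ml
mode: bacteriostatic
kappa: 2      # pharmacodynamic Hill exponent
m0: 2.5       # ancestral strain MIC, ug/ml
delta_max: 0.5   # maximal kill rate (bactericidal), 1/h
mu_res: 2.0e-6   # per-division resistance step probability
lambda: 2        # MIC multiplier per resistance level
L: 8             # maximum resistance level
mu_rev:          # per-division reversion probability, per strain
  TRP: 0.0
  TYR: 2.0e-6
cost_rev: 0.5    # relative growth-rate cost of prototrophy
alpha: 1      # OD600 per 1e9 cells/ml
sigma: 0.05   # lognormal OD noise (sdlog)
dt: 0.1       # integration step, h
batch_h: 72   # batch duration, h
dilution: 0.04        # serial-transfer dilution, 40 ul into 1000 ul
supplement_uM: 100    # amino-acid supplement in monoculture medium, uM
pool0_coculture: 2    # amino acid carried over with coculture inoculum, uM
od_inoculum: 0.004    # OD600 of a freshly inoculated culture
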