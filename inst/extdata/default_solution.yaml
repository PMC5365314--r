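# Default bathing-solution recipe: 25 mM imidazole-buffered activating
# solution series, pH 7.1, 20 C, ionic strength 0.2 M.
# Binding constants are APPARENT 1:1 association constants (1/M) at those
# conditions. They are package defaults in the range of standard
# MaxChelator-style tabulations, NOT measured values; replace with
# lab-specific constants when available.
total_ca: 0.0        # molar; varied 0-10 mM across the solution series
total_egta: 0.010    # molar (0.2 mM in pre-activating solution)
total_atp: 0.005     # molar (as MgATP)
free_mg: 0.001       # molar, clamped; total Mg is an output
ph: 7.1
temperature_c: 20
ionic_strength: 0.2  # molar
constants:
  k_ca_egta: 3.72e+06
  k_mg_egta: 50.1
  k_ca_atp: 5.01e+03
  k_mg_atp: 7.94e+03
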