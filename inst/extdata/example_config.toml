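# Example run configuration for the fibertopo CLI.
# Unset keys fall back to package defaults, which are materialized into the
# JSON provenance sidecar of every run.

[fiber]
L = 40              # free linker length, bp
L_NCP = 147         # core length, bp (146 for "601" arrays)
n_nucleosomes = 12
circular = false
family_hint = "T2"

[energy]
stacking_depth = 18.0      # kT
stacking_distance = 7.0    # nm, center-to-center
stacking_width = 0.5       # nm

[mc]
temperature = 1.0          # kT
n_steps = 200000
seed = 1
record_every = 500

[observables]
lambda_nm = 4.0            # FLD exponential drop constant
fld_min = 250
fld_max = 400
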