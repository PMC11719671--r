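# Scoring configuration for the angiogenic activity index.
#
# `weights` is the slot for predictive-importance factors: parameters judged
# especially informative for complex vascular architecture can be given
# factor 2 (all parameters default to 1). In `literal` subindex mode the
# weighted sum is divided by the parameter count, so factor-2 parameters can
# push a subindex (and the final index) beyond +/-1.
day_early: 4
day_late: 7
control_group: control
subindex_mode: literal     # literal: (1/n) * sum(w_i * AAI_i); or normalized
aggregation: per_donor     # per_donor: index per donor, then averaged; or pooled
degenerate_policy: error   # zero control change: error (or epsilon fallback)
weights: {}
# example:
# weights:
#   vessel_density: 2
#   n_loops: 2
orientation: {}
# example (score a declining primary-vessel share as pro-angiogenic):
# orientation:
#   vessel_structure_pct: -1
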