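# Small example simulation: one donor, two rings per group, a control and a
# stimulated secretome-like treatment. Rates are per-ring kinetics; the
# treatment multiplier scales elongation and branching.
days: [1, 4, 7]
rings_per_group: 2
donors: 1
ring_radius: 540        # um; ~3.4 mm circumference explant
seed: 1
donor_sd: 0
groups:
  control:
    seed_density: 6.0       # initial vessels per mm circumference by day 7
    elongation: 100         # um/day
    direction_jitter: 20    # degrees (per-day sd)
    branching_rate: 1.5     # branch events per mm grown
    anastomosis_prob: 0.15
    capture_radius: 15      # um
  treated:
    seed_density: 6.0
    elongation: 100
    direction_jitter: 20
    branching_rate: 1.5
    anastomosis_prob: 0.15
    capture_radius: 15
    treatment_multiplier: 1.5
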