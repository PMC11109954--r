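# Shared fixtures: a well-conditioned demo rate set and reduced-scale
# configurations used across tests.

demo_rates <- function() kinetic_rates(20, 40, 100, 200)

# burn-in shortened for speed: initial states/positions are stationary, and
# the suite checks this equivalence explicitly (test-mcdda-sim.R)
fast_imaging <- function(...) imaging_config(equilibration = 0.01, ...)

quick_fit_config <- function(seed = 777) {
  fit_config(n_particles = 20000, pre_particles = 6000, pre_evals = 130,
             pre_rounds = 3, floor_factor = 1.25, noise_reps = 8,
             max_iter = 8, seed = seed)
}
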