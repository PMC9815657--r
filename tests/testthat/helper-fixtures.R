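# Shared cheap fixtures: a coarse (but spec-valid) 10 kHz protocol keeps the
# per-test simulation cost low; full-scale protocols are exercised in the
# acceptance tests.

fast_protocol <- function(max_pa = 600, ...) {
  step_protocol(max_pa = max_pa, sampling_rate_hz = 10000, ...)
}

noiseless_truth <- function(rheobase_pa = 230, gain_hz_na = 100,
                            rin_mohm = 100, cm_pf = 100, ...) {
  neuron_truth(rheobase_pa, gain_hz_na, rin_mohm, cm_pf,
               noise_sd_mv = 0, ...)
}

# a small planted-effect gait configuration used across OSC-PLS tests
planted_gait <- function(seed = 2, effect = 5) {
  simulate_gait_table(
    gait_sim_config(n_per_group = c(6, 6), n_vars = 20, n_informative = 1,
                    effect_sizes = effect, noise_sd = 0.3, latent_rank = 3),
    seed = seed
  )
}

null_gait <- function(seed) {
  simulate_gait_table(
    gait_sim_config(n_per_group = c(4, 4), trials_per_animal = 2,
                    n_vars = 10, n_informative = 0, latent_rank = 3),
    seed = seed
  )
}
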