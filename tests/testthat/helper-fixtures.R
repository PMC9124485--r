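# shared fixtures built in code

# small, fully deterministic generator configuration (no measurement noise,
# no inter-fish variation, no tracker floor) for exact-recovery tests
noiseless_config <- function(n_fish = 3, seed = 11, ...) {
  synth_config(n_fish = n_fish, noise_sigma_mo2 = 0, smr_cv = 0, b_cv = 0,
               activity_floor = 0, intervals_per_phase = 20, seed = seed, ...)
}

# default-noise configuration scaled down for speed
small_config <- function(n_fish = 6, seed = 7, ...) {
  synth_config(n_fish = n_fish, intervals_per_phase = 15, seed = seed, ...)
}

# the full-cooling interval on the default condition labels
full_cooling_interval <- function(warm = "acute_14", cold = "acute_2.5") {
  data.frame(label = "full_cooling", condition_warm = warm,
             condition_cold = cold, stringsAsFactors = FALSE)
}
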