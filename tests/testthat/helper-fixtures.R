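# Shared fixtures: all generated in code at test time.

# a tiny 2x2x2 battery design (8 pairs) for fast structural tests
tiny_design <- function() {
  default_battery_design(f0_hz = c(150, 250), n_min = 2:3, n_harmonics = 2:3)
}

# a pair with F0 rising and F_SP falling (second member lowers n_min is not
# allowed, so build it by swapping the canonical construction)
example_pair <- function() {
  a <- harmonic_complex(200, 3, 3)          # top harmonic 1000 Hz
  b <- harmonic_complex(250, 2, 3)          # 250*4 = 1000 Hz, F0 up, FSP down
  sound_pair(a, b, "ex1")
}

# small study bundle shared across pipeline tests
small_bundle <- function(n = 12, seed = 5, n_rev = 150) {
  gen_study(n_subjects = n, seed = seed, n_revolutions = n_rev)
}

# quick posterior fit whose draws are replaced by fixed values, for exact
# checks of the prediction path
zero_draw_fit <- function(fit, values = list()) {
  fit$draws[] <- 0
  for (nm in names(values)) fit$draws[, nm] <- values[[nm]]
  fit
}
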