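# Shared fixtures: all built in code, sized for seconds-scale tests.

# A tiny, learnable band task: two classes, small TFRs.
tiny_band_task <- function(n_per = 24, shape = c(16L, 32L), seed = 42,
                           power_ratio_db = 6, noise_sd = 0.05) {
  cfg <- synthetic_config(n_classes = 2, samples_per_class = n_per,
                          tfr_shape = shape,
                          class_bands = list(c(0.35, 0.3), c(0.7, 0.25)),
                          nuisance_band = c(-0.5, 0.4),
                          power_ratio_db = power_ratio_db,
                          noise_sd = noise_sd, seed = seed)
  gen_band_task(cfg)
}

# A tiny encoder spec so forward/backward tests run in milliseconds.
tiny_encoder <- function() {
  encoder_spec(channels = c(4L, 6L, 8L), head_hidden = 12L, embed_dim = 8L)
}

# Random unit-norm embedding matrix.
random_unit_rows <- function(n, d, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- matrix(rnorm(n * d), n, d)
  z / sqrt(rowSums(z^2))
}
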