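# Shared fixtures and independent oracles, all built in code.

# Independent Haar oracle: full orthonormal cascade by pairwise
# averaging/differencing (three averaging levels, then one differencing
# step), kept separate from the package's block-sum implementation.
haar_cascade_oracle <- function(x) {
  a <- x
  for (lev in 1:3) {
    a <- (a[seq(1, length(a), 2)] + a[seq(2, length(a), 2)]) / sqrt(2)
  }
  (a[seq(1, length(a), 2)] - a[seq(2, length(a), 2)]) / sqrt(2)
}

# A small noise-free single-population spec for shape tests.
quiet_population <- function(amplitude = 1, asymmetry = 0, baseline = 0,
                             extinction_depth = 0, peak_shift = 0,
                             diameter_mean = 10, diameter_sd = 0,
                             n_channels = 4) {
  population_spec("only", 1, diameter_mean, diameter_sd,
                  channels = rep(list(channel_morphology(
                    amplitude = amplitude, asymmetry = asymmetry,
                    baseline = baseline, extinction_depth = extinction_depth,
                    peak_shift = peak_shift, noise_sd = 0)), n_channels),
                  stain_mean = c(1, 1))
}

# A moderate demo stream cached per session (used by several test files).
demo_stream <- local({
  cache <- NULL
  function(rate = 500, duration = 4, seed = 101) {
    if (is.null(cache)) {
      cache <<- simulate_stream(demo_populations(), rate, duration,
                                optical_config(), seed = seed)
    }
    cache
  }
})

# Cached sort model fitted on the demo stream (k = 6 per channel).
demo_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_sort_model(wavelet_features(demo_stream()), k = 6, seed = 1)
    }
    cache
  }
})

# Well-separated isotropic Gaussian blobs in p dimensions.
make_blobs <- function(n_per, means, sd = 0.05, seed = 7) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    matrix(stats::rnorm(n_per * ncol(means), 0, sd), n_per) +
      matrix(means[i, ], n_per, ncol(means), byrow = TRUE)
  }))
  list(x = x, label = rep(seq_len(nrow(means)), each = n_per), means = means)
}
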