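test_that("area, height and width match direct summation", {
  # rectangular pulse: height 2 over 10 samples on a zero baseline
  rect <- c(rep(0, 5), rep(2, 10), rep(0, 5))
  expect_equal(compute_ahw(rect, baseline_estimate = 0),
               c(A = 20, H = 2, W = 10))
  expect_equal(compute_ahw(rep(0, 20), baseline_estimate = 0),
               c(A = 0, H = 0, W = 0))
  tri <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  expect_equal(compute_ahw(tri, baseline_estimate = 0),
               c(A = 16, H = 4, W = 3))
  # nonzero baseline is subtracted before clipping
  expect_equal(compute_ahw(tri + 5, baseline_estimate = 5),
               c(A = 16, H = 4, W = 3))
  # edge-estimated baseline recovers the DC level of a centred pulse
  w <- c(rep(3, 10), 3 + tri, rep(3, 10))
  expect_equal(compute_ahw(w), c(A = 16, H = 4, W = 3))
})

test_that("negative-going (extinction) pulses yield zero A/H/W", {
  dip <- c(rep(0, 8), -1, -2, -1, rep(0, 8))
  expect_equal(compute_ahw(dip, baseline_estimate = 0), c(A = 0, H = 0, W = 0))
})

test_that("Haar coefficients equal the orthonormal cascade oracle", {
  expect_equal(haar_coefficients(rep(3.7, 80)), rep(0, 5))
  # one 16-sample block stepping 4 -> 0 halfway: (32 - 0)/4 = 8
  x <- c(rep(4, 8), rep(0, 8), rep(0, 64))
  expect_equal(haar_coefficients(x), c(8, 0, 0, 0, 0))
  expect_length(haar_coefficients(stats::rnorm(80)), 5)
  expect_length(haar_coefficients(stats::rnorm(160)), 10)
  set.seed(42)
  for (i in 1:50) {
    w <- stats::rnorm(80)
    expect_equal(haar_coefficients(w), haar_cascade_oracle(w), tolerance = 1e-12)
  }
  expect_error(haar_coefficients(stats::rnorm(81)), "multiple of 16")
  expect_error(haar_coefficients(numeric(0)), "multiple of 16")
})

test_that("the approximation branch carries the block sums", {
  x <- c(rep(4, 8), rep(0, 8), rep(1, 64))
  expect_equal(haar_coefficients(x, type = "approximation"),
               c(32 / 4, rep(16 / 4, 4)))
})

test_that("Haar transform is linear", {
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(80); y <- stats::rnorm(80)
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    expect_equal(haar_coefficients(a * x + b * y),
                 a * haar_coefficients(x) + b * haar_coefficients(y),
                 tolerance = 1e-10)
  }
})

test_that("translating a pulse by one block rotates the coefficients", {
  set.seed(2)
  pulse <- stats::rnorm(16)
  x <- c(rep(0, 16), pulse, rep(0, 48))
  y <- c(rep(0, 32), pulse, rep(0, 32))  # shifted by 16 samples
  cx <- haar_coefficients(x)
  cy <- haar_coefficients(y)
  expect_equal(cy, c(0, cx[1:4]))
})

test_that("streaming transform matches the batch transform on aligned windows", {
  set.seed(3)
  for (i in 1:10) {
    pulses <- replicate(10, stats::rnorm(80), simplify = FALSE)
    stream <- unlist(pulses)
    batch <- unlist(lapply(pulses, haar_coefficients))
    expect_equal(streaming_haar(stream, offset = 0), batch, tolerance = 1e-12)
  }
})

test_that("streaming offset changes which block straddles a step", {
  stream <- c(rep(0, 24), rep(4, 56))
  c0 <- streaming_haar(stream, offset = 0)
  c8 <- streaming_haar(stream, offset = 8)
  expect_false(isTRUE(all.equal(c0[1:4], c8[1:4])))
  # direct computation at both offsets
  expect_equal(c0, haar_coefficients(stream))
  expect_equal(c8, haar_coefficients(stream[9:72]))
})

test_that("streaming transform handles degenerate streams", {
  expect_equal(streaming_haar(rep(5, 160), offset = 7), rep(0, 9))
  expect_length(streaming_haar(stats::rnorm(10), offset = 0), 0)
  expect_length(streaming_haar(stats::rnorm(18), offset = 5), 0)
  expect_error(streaming_haar(stats::rnorm(80), offset = 16), "offset")
})

test_that("W is amplitude-invariant while A and H scale", {
  base <- simulate_pulse(quiet_population(amplitude = 1), seed = 4, jitter = 0L)
  tall <- simulate_pulse(quiet_population(amplitude = 3), seed = 4, jitter = 0L)
  fb <- compute_ahw(base$waveforms[1, ], baseline_estimate = 0)
  ft <- compute_ahw(tall$waveforms[1, ], baseline_estimate = 0)
  expect_equal(ft[["W"]], fb[["W"]])
  expect_equal(ft[["H"]] / fb[["H"]], 3, tolerance = 1e-12)
  expect_equal(ft[["A"]] / fb[["A"]], 3, tolerance = 1e-12)
})

test_that("stream-level feature matrices agree with per-event computation", {
  s <- demo_stream()
  W <- wavelet_features(s)
  expect_equal(dim(W), c(n_events(s), 20))
  i <- c(1, 17, n_events(s))
  for (ev in i) {
    for (ch in 1:4) {
      expect_equal(unname(W[ev, (ch - 1) * 5 + 1:5]),
                   haar_coefficients(as.numeric(s$waveforms[ev, ch, ])))
    }
  }
  A <- ahw_features(s)
  expect_equal(unname(unlist(A[1, 1:3])),
               unname(compute_ahw(as.numeric(s$waveforms[1, 1, ]))))
  expect_true(all(c("stain1", "stain2") %in% names(A)))
})
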