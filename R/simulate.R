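# Pulse-shape simulator: skewed-bell transit profiles on a sampled window.
# The profile is a skew-normal kernel normalized to unit peak; a physical
# Mie/scattering computation is out of scope.

# Unit-peak (skew-)bell evaluated at sample indices 1..n. `center` may be
# fractional; sigma is in samples. alpha = 0 gives a symmetric Gaussian.
.bell_profile <- function(n, center, sigma, alpha = 0) {
  z <- (seq_len(n) - center) / sigma
  f <- exp(-z^2 / 2)
  if (alpha != 0) f <- f * 2 * stats::pnorm(alpha * z)
  m <- max(f)
  if (m > 0) f / m else f
}

# sigma such that the bell's above-half-max width tracks the transit length:
# FWHM of a Gaussian is 2.355 sigma; we set FWHM = transit length.
.transit_sigma <- function(n_transit) n_transit / (2 * sqrt(2 * log(2)))

# skew parameter from the dimensionless asymmetry in [-1, 1]
.skew_alpha <- function(asymmetry) 5 * asymmetry

#' Simulate one triggered event
#'
#' Draws a particle diameter from the population's diameter distribution and
#' renders, for every channel, a waveform of `optics$n_samples` samples:
#' baseline + amplitude x skewed bell of above-half-max width equal to the
#' transit length ([transit_samples()]), peak offset by `peak_shift` x transit
#' length, minus an extinction dip (a symmetric bell of the same width scaled
#' by `extinction_depth`), plus i.i.d. Gaussian noise. The pulse is centred in
#' the window up to an integer trigger-jitter offset drawn uniformly from
#' `-jitter..jitter` samples.
#'
#' @param pop a [population_spec()] whose `channels` length matches
#'   `optics$n_channels`.
#' @param optics an [optical_config()].
#' @param seed optional integer seed for reproducibility.
#' @param jitter maximum trigger jitter, samples (uniform over
#'   `-jitter..jitter`).
#' @return A list of class `event_record` with fields `waveforms`
#'   (n_channels x n_samples matrix), `timestamp`, `true_label`, `diameter`,
#'   `truncated` (TRUE when the transit exceeds the trigger window) and
#'   `stain_intensities`.
#' @export
simulate_pulse <- function(pop, optics = optical_config(), seed = NULL,
                           jitter = 2L) {
  stopifnot(inherits(pop, "population_spec"), inherits(optics, "optical_config"))
  if (length(pop$channels) != optics$n_channels) {
    stop("population has ", length(pop$channels), " channel morphologies but ",
         "optics declares ", optics$n_channels, " channels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- max(0.1, stats::rnorm(1, pop$diameter_mean, pop$diameter_sd))
  jit <- if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L else 0L
  w <- .render_waveforms(pop, optics, d, jit)
  stains <- if (!is.null(pop$stain_mean)) {
    stats::rnorm(2, pop$stain_mean, pop$stain_sd)
  } else NULL
  structure(list(event_id = 0L, timestamp = 0, waveforms = w$waveforms,
                 true_label = pop$label, diameter = d, truncated = w$truncated,
                 stain_intensities = stains),
            class = "event_record")
}

# Render all channel waveforms for one event (noise included).
.render_waveforms <- function(pop, optics, diameter, jit) {
  n <- optics$n_samples
  L <- transit_samples(diameter, optics)
  truncated <- L > n
  sigma <- .transit_sigma(L)
  waveforms <- matrix(0, nrow = optics$n_channels, ncol = n,
                      dimnames = list(optics$channel_names, NULL))
  for (ch in seq_len(optics$n_channels)) {
    m <- pop$channels[[ch]]
    center <- (n + 1) / 2 + jit + m$peak_shift * L
    x <- rep(m$baseline, n)
    if (m$amplitude != 0) {
      x <- x + m$amplitude * .bell_profile(n, center, sigma, .skew_alpha(m$asymmetry))
    }
    if (m$extinction_depth > 0) {
      x <- x - m$extinction_depth * .bell_profile(n, center, sigma, 0)
    }
    if (m$noise_sd > 0) x <- x + stats::rnorm(n, 0, m$noise_sd)
    waveforms[ch, ] <- x
  }
  list(waveforms = waveforms, truncated = truncated)
}

#' Simulate a timed event stream
#'
#' Event arrivals form a homogeneous Poisson process at `event_rate`;
#' population labels are drawn independently with the configured abundances.
#' Each event is rendered with [simulate_pulse()]'s waveform model. When the
#' populations define stain means, every event carries a pair of stain
#' intensities forming well-separated Gaussian clusters per label, so that
#' reference labels can be re-derived by rectangular gating.
#'
#' @param pops list of [population_spec()]; abundances must sum to 1.
#' @param event_rate mean event rate, events/s (> 0).
#' @param duration acquired duration, s (> 0).
#' @param optics an [optical_config()].
#' @param seed integer seed; the whole stream is a deterministic function of
#'   (pops, event_rate, duration, optics, seed).
#' @param jitter maximum trigger jitter in samples.
#' @return An object of class `pulse_stream`: a list with `waveforms`
#'   (n_events x n_channels x n_samples array), `timestamp` (strictly
#'   increasing, s), `label`, `diameter`, `truncated`, `stains` (n x 2 matrix
#'   or NULL), `optics`.
#' @export
simulate_stream <- function(pops, event_rate, duration,
                            optics = optical_config(), seed = NULL,
                            jitter = 2L) {
  stopifnot(is.list(pops), all(vapply(pops, inherits, TRUE, "population_spec")))
  if (event_rate <= 0) stop("event_rate must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  ab <- vapply(pops, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-8) stop("population abundances must sum to 1", call. = FALSE)
  for (p in pops) {
    if (length(p$channels) != optics$n_channels) {
      stop("population '", p$label, "' does not match optics channel count",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  # Poisson arrivals: exponential gaps until the duration is exceeded
  ts <- numeric(0); t <- 0
  repeat {
    # draw gaps in blocks for speed
    gaps <- stats::rexp(max(64, ceiling(event_rate * duration * 0.2)), event_rate)
    tt <- t + cumsum(gaps)
    ts <- c(ts, tt[tt <= duration])
    t <- tt[length(tt)]
    if (t > duration) break
  }
  n <- length(ts)
  labels <- vapply(pops, `[[`, character(1), "label")
  idx <- sample.int(length(pops), n, replace = TRUE, prob = ab)

  n_ch <- optics$n_channels; n_s <- optics$n_samples
  waveforms <- array(0, dim = c(n, n_ch, n_s),
                     dimnames = list(NULL, optics$channel_names, NULL))
  diam <- numeric(n); trunc <- logical(n)
  jits <- if (jitter > 0) sample.int(2L * jitter + 1L, n, replace = TRUE) - jitter - 1L
          else integer(n)
  for (i in seq_len(n)) {
    p <- pops[[idx[i]]]
    diam[i] <- max(0.1, stats::rnorm(1, p$diameter_mean, p$diameter_sd))
    w <- .render_waveforms(p, optics, diam[i], jits[i])
    waveforms[i, , ] <- w$waveforms
    trunc[i] <- w$truncated
  }

  stains <- NULL
  if (all(vapply(pops, function(p) !is.null(p$stain_mean), TRUE)) && n > 0) {
    mu <- t(vapply(pops, `[[`, numeric(2), "stain_mean"))
    sd <- vapply(pops, `[[`, numeric(1), "stain_sd")
    stains <- mu[idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n), n, 2) * sd[idx]
    colnames(stains) <- c("stain1", "stain2")
  }

  structure(list(waveforms = waveforms, timestamp = ts,
                 label = labels[idx], diameter = diam, truncated = trunc,
                 stains = stains, optics = optics),
            class = "pulse_stream")
}

#' @export
print.pulse_stream <- function(x, ...) {
  cat(sprintf("Pulse stream: %d events, %d channels x %d samples\n",
              n_events(x), x$optics$n_channels, x$optics$n_samples))
  if (n_events(x) > 0) {
    cat(sprintf("  span %.4g s; labels: %s\n",
                max(x$timestamp),
                paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Number of events in a pulse stream
#' @param stream a `pulse_stream`.
#' @return integer event count.
#' @export
n_events <- function(stream) {
  stopifnot(inherits(stream, "pulse_stream"))
  length(stream$timestamp)
}

#' Subset a pulse stream by event index
#' @param stream a `pulse_stream`.
#' @param i 1-based event indices to keep.
#' @return a `pulse_stream` with the selected events, order preserved.
#' @export
subset_stream <- function(stream, i) {
  stopifnot(inherits(stream, "pulse_stream"))
  structure(list(waveforms = stream$waveforms[i, , , drop = FALSE],
                 timestamp = stream$timestamp[i],
                 label = stream$label[i], diameter = stream$diameter[i],
                 truncated = stream$truncated[i],
                 stains = if (!is.null(stream$stains))
                   stream$stains[i, , drop = FALSE] else NULL,
                 optics = stream$optics),
            class = "pulse_stream")
}

#' Mean pulse shapes per population label
#'
#' Base-graphics QC figure: one panel per channel, average waveform per label.
#' @param x a `pulse_stream` with labels.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pulse_stream <- function(x, ...) {
  labs <- sort(unique(x$label))
  nch <- x$optics$n_channels
  op <- graphics::par(mfrow = grDevices::n2mfrow(nch), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  t_us <- (seq_len(x$optics$n_samples) - 1) / x$optics$sampling_rate * 1e6
  for (ch in seq_len(nch)) {
    avg <- sapply(labs, function(l)
      colMeans(x$waveforms[x$label == l, ch, , drop = FALSE][, 1, ]))
    graphics::matplot(t_us, avg, type = "l", lty = 1,
                      xlab = "time (us)", ylab = "intensity (a.u.)",
                      main = x$optics$channel_names[ch], ...)
    graphics::legend("topright", legend = labs, lty = 1,
                     col = seq_along(labs), bty = "n", cex = 0.8)
  }
  invisible(x)
}
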