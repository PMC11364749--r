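# End-to-end workflow: simulate -> features -> gate -> cluster -> rank ->
# sort -> report, with a single human-readable (YAML) run configuration and
# one explicit seed from which every stage's randomness derives.

#' Run configuration
#'
#' Collects every tunable of the pipeline. Validation happens here, before
#' any stage runs; the full configuration is serialized into the run log.
#'
#' @param optics an [optical_config()].
#' @param populations list of [population_spec()]s (abundances sum to 1).
#' @param event_rate mean event rate, events/s.
#' @param duration acquisition duration, s.
#' @param k clusters per channel (1..8; default 6).
#' @param threshold_frac ranking-B enrichment threshold as a fraction of the
#'   maximum achievable enrichment.
#' @param top_n sort clusters selected per population.
#' @param min_size_frac minimum preferred cluster size (fraction of events).
#' @param timing a [timing_config()].
#' @param seed master integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(optics = optical_config(),
                       populations = demo_populations(),
                       event_rate = 1000, duration = 10,
                       k = 6L, threshold_frac = 0.75, top_n = 3L,
                       min_size_frac = 0.01, timing = timing_config(),
                       seed = 1L) {
  stopifnot(inherits(optics, "optical_config"), inherits(timing, "timing_config"))
  if (any(k < 1L) || any(k > 8L)) stop("k must lie in 1..8", call. = FALSE)
  if (event_rate <= 0 || duration <= 0) {
    stop("event_rate and duration must be > 0", call. = FALSE)
  }
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop("threshold_frac must lie in (0, 1]", call. = FALSE)
  }
  ab <- vapply(populations, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-8) stop("abundances must sum to 1", call. = FALSE)
  structure(list(optics = optics, populations = populations,
                 event_rate = event_rate, duration = duration,
                 k = as.integer(k), threshold_frac = threshold_frac,
                 top_n = as.integer(top_n), min_size_frac = min_size_frac,
                 timing = timing, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  opt <- do.call(optical_config,
                 y$optics[c("beam_width", "flow_speed", "sampling_rate",
                            "window_length", "n_channels", "channel_names")])
  pops <- lapply(y$populations, function(p) {
    chans <- lapply(p$channels, function(m) do.call(channel_morphology, m))
    population_spec(p$label, p$abundance, p$diameter_mean, p$diameter_sd,
                    channels = chans,
                    stain_mean = if (!is.null(p$stain_mean)) unlist(p$stain_mean),
                    stain_sd = if (!is.null(p$stain_sd)) p$stain_sd else 0.05)
  })
  tim <- do.call(timing_config,
                 y$timing[c("decision_latency", "actuation_delay",
                            "engage_duration", "disengage_duration",
                            "travel_time", "refractory",
                            "deflect_during_disengage", "startup_discard")])
  run_config(optics = opt, populations = pops, event_rate = y$event_rate,
             duration = y$duration, k = y$k,
             threshold_frac = y$threshold_frac, top_n = y$top_n,
             min_size_frac = y$min_size_frac, timing = tim, seed = y$seed)
}

# Derive reference labels from stain intensities by rectangular gating,
# mirroring how ground truth is established with a stain pair on the real
# instrument: one auto-placed box per population, centred on its stain mean.
.stain_gates <- function(populations, half_width = 0.3) {
  lapply(populations, function(p) {
    rect_gate("stain1", "stain2",
              p$stain_mean[1] - half_width, p$stain_mean[1] + half_width,
              p$stain_mean[2] - half_width, p$stain_mean[2] + half_width)
  })
}

#' Reference labels by stain gating
#'
#' Applies one rectangular stain gate per population (auto-placed on the
#' configured stain means) and returns per-event labels; events outside all
#' gates get `NA`.
#'
#' @param stream a `pulse_stream` with stains.
#' @param populations the [population_spec()]s defining the gates.
#' @param half_width half-width of each gate box in stain units.
#' @return list with `labels` (per event, NA outside all gates) and `gates`
#'   (named list of [index_list()]s).
#' @export
gate_labels <- function(stream, populations, half_width = 0.3) {
  stopifnot(!is.null(stream$stains))
  feat <- as.data.frame(stream$stains)
  gates <- .stain_gates(populations, half_width)
  labels <- rep(NA_character_, n_events(stream))
  out <- list()
  for (i in seq_along(populations)) {
    il <- apply_gate(feat, gates[[i]], name = populations[[i]]$label)
    labels[il$indices + 1L] <- populations[[i]]$label
    out[[populations[[i]]$label]] <- il
  }
  list(labels = labels, gates = out)
}

#' Run the full pipeline
#'
#' Simulates an acquisition, extracts features, derives reference labels by
#' stain gating, fits the per-channel cluster models, enumerates conjunction
#' clusters, ranks and selects sort clusters, virtually sorts the top
#' cluster of each population on a freshly simulated sort stream, and
#' re-analyses the sorted samples. When `out_dir` is given, all artifacts
#' are written: pulse and coefficient binaries, the FCS feature file, the
#' centroid table, gate index files, the selection table and a YAML run log.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `pipeline_result` with `stream`, `coeffs`,
#'   `features`, `labels`, `model`, `clusters`, `selection`, `sorts` (per
#'   population: `outcome` + `reanalysis`), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  stream <- simulate_stream(config$populations, config$event_rate,
                            config$duration, config$optics,
                            seed = config$seed)
  if (n_events(stream) < max(config$k) * 10) {
    stop("run_pipeline: too few events (", n_events(stream),
         ") for clustering; increase event_rate or duration", call. = FALSE)
  }
  coeffs <- wavelet_features(stream)
  feats <- ahw_features(stream)
  gl <- gate_labels(stream, config$populations)
  labels <- gl$labels
  labels[is.na(labels)] <- "ungated"

  model <- fit_sort_model(coeffs, k = config$k, seed = config$seed)
  assignment <- predict(model)
  clusters <- enumerate_conjunctions(assignment, k = model$k, order = 2L)

  pop_names <- vapply(config$populations, `[[`, character(1), "label")
  selection <- rank_and_select(labels, clusters,
                               threshold_frac = config$threshold_frac,
                               top_n = config$top_n,
                               min_size_frac = config$min_size_frac,
                               populations = pop_names)

  # virtual sort of the top-selected cluster per population on a fresh stream
  sort_stream <- simulate_stream(config$populations, config$event_rate,
                                 config$duration, config$optics,
                                 seed = config$seed + 1L)
  sort_assign <- predict(model, sort_stream)
  sorts <- list()
  for (p in names(selection$selected)) {
    if (p == "ungated" || nrow(selection$selected[[p]]) == 0) next
    cl <- clusters[[selection$selected[[p]]$cluster[1]]]
    outcome <- run_sort(sort_stream$timestamp, sort_assign, cl,
                        timing = config$timing, labels = sort_stream$label)
    sorts[[p]] <- list(cluster = cl$name, outcome = outcome,
                       reanalysis = reanalyze(outcome, sort_stream$label))
  }

  res <- structure(list(stream = stream, coeffs = coeffs, features = feats,
                        labels = labels, model = model, clusters = clusters,
                        selection = selection, sorts = sorts, config = config),
                   class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(...) file.path(out_dir, ...)
    write_pulses(stream, f("pulses.bin"))
    write_coeffs(coeffs, f("coefficients.bin"), config$optics$n_channels)
    write_fcs(feats, f("features.fcs"))
    write_centroids(model, f("centroids.tsv"))
    for (nm in names(gl$gates)) {
      write_index(gl$gates[[nm]], f(paste0("gate_", nm, ".txt")))
    }
    write_selection_table(selection, clusters, f("sort_clusters.tsv"))
    for (p in names(sorts)) {
      o <- sorts[[p]]$outcome
      write_index(index_list(paste0("sorted_", p), sort(c(o$sorted, o$co_sorted))),
                  f(paste0("sorted_", p, ".txt")))
    }
    log <- list(config = "run_config.yaml",
                n_events = n_events(stream),
                n_candidate_clusters = length(clusters),
                n_selected = sum(vapply(selection$selected, nrow, integer(1))),
                sorts = lapply(sorts, function(s)
                  list(cluster = s$cluster,
                       n_sorted = length(s$outcome$sorted),
                       n_co_sorted = length(s$outcome$co_sorted),
                       yield = s$outcome$yield)))
    write_run_config(config, f("run_config.yaml"))
    yaml::write_yaml(log, f("run_log.yaml"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d events, %d candidate conjunction clusters\n",
              n_events(x$stream), length(x$clusters)))
  print(x$selection)
  for (p in names(x$sorts)) {
    s <- x$sorts[[p]]
    tgt <- s$reanalysis$fractions[p]
    cat(sprintf("  sorted %-4s via %-24s purity(%s) = %.3f, yield = %.3f\n",
                p, s$cluster, p,
                if (is.null(tgt) || is.na(tgt)) NA_real_ else tgt,
                s$outcome$yield))
  }
  invisible(x)
}
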