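# Per-channel k-means in wavelet-coefficient space and the nearest-centroid
# rule that the signal-processing electronics apply in real time. Lloyd's
# algorithm with k-means++ seeding is implemented here because the decision
# rule must reproduce the on-line behaviour exactly: fixed seed, movement
# tolerance 1e-6, at most 300 iterations, empty clusters re-seeded with the
# farthest point, no events excluded. Cluster ids are 0-based, as printed on
# the instrument and in sort-cluster listings.

# squared Euclidean distances, n x k
.dist2 <- function(x, centers) {
  n <- nrow(x); k <- nrow(centers)
  d2 <- matrix(rowSums(x^2), n, k) +
    matrix(rowSums(centers^2), n, k, byrow = TRUE) -
    2 * x %*% t(centers)
  pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# proportional to squared distance to the nearest chosen centre.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- .dist2(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, .dist2(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

# one Lloyd run from a given init; returns centers, assignment, inertia and
# the per-iteration inertia trace (non-increasing by construction)
.lloyd <- function(x, centers, tol = 1e-6, max_iter = 300L) {
  k <- nrow(centers)
  iter <- 0L
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    d2 <- .dist2(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    trace[iter] <- sum(d2[cbind(seq_len(nrow(x)), assign)])
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # empty cluster: re-seed with the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        new_centers[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (movement < tol || iter >= max_iter) break
  }
  d2 <- .dist2(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  list(centers = centers, assignment = assign,
       inertia = sum(d2[cbind(seq_len(nrow(x)), assign)]), iterations = iter,
       inertia_trace = trace)
}

#' Fit a single-channel cluster model
#'
#' k-means (Lloyd's algorithm, k-means++ initialization) on one channel's
#' wavelet coefficients. All events are included; `nstart` restarts are run
#' and the solution with the lowest inertia kept.
#'
#' @param coeffs n x p numeric matrix of wavelet coefficients (p = 5 for the
#'   default 80-sample window).
#' @param k number of clusters, between 1 and 8 (default 6, matching the
#'   number of pulse-shape groups typically defined per scattering angle).
#' @param seed integer seed controlling the initialization.
#' @param nstart number of k-means++ restarts (best inertia kept).
#' @param tol convergence tolerance on maximum centroid movement.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param scale if TRUE, columns are standardized before clustering
#'   (off by default: the instrument clusters raw coefficients).
#' @param channel channel name stored in the model.
#' @return An object of class `channel_model`: list with `channel`, `k`,
#'   `centroids` (k x p, rows named by 0-based cluster id), `assignment`
#'   (0-based per event), `inertia`, `iterations`, `seed`.
#' @export
fit_channel <- function(coeffs, k = 6L, seed = NULL, nstart = 10L,
                        tol = 1e-6, max_iter = 300L, scale = FALSE,
                        channel = "CH") {
  coeffs <- as.matrix(coeffs)
  if (!all(is.finite(coeffs))) stop("fit_channel: non-finite coefficients", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("fit_channel: k must lie in 1..8", call. = FALSE)
  if (nrow(coeffs) < k) {
    stop("fit_channel: need at least k = ", k, " events, got ", nrow(coeffs),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- coeffs
  ctr <- NULL; scl <- NULL
  if (scale) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k), tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  centroids <- best$centers
  if (scale) centroids <- sweep(sweep(centroids, 2, scl, "*"), 2, ctr, "+")
  rownames(centroids) <- as.character(0:(k - 1))
  colnames(centroids) <- colnames(coeffs)
  structure(list(channel = channel, k = k, centroids = centroids,
                 assignment = best$assignment - 1L, inertia = best$inertia,
                 iterations = best$iterations,
                 inertia_trace = best$inertia_trace, seed = seed,
                 scaled = scale, scale_center = ctr, scale_sd = scl),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("Channel model '%s': k = %d, inertia = %.4g (%d iterations)\n",
              x$channel, x$k, x$inertia, x$iterations))
  invisible(x)
}

#' Nearest-centroid assignment
#'
#' The real-time sort decision primitive: each coefficient vector is assigned
#' to the closest centroid by Euclidean distance, ties broken by the lowest
#' cluster id.
#'
#' @param coeffs a single coefficient vector or an n x p matrix.
#' @param model a fitted [fit_channel()] model.
#' @return 0-based cluster id(s).
#' @export
assign_nearest <- function(coeffs, model) {
  stopifnot(inherits(model, "channel_model"))
  x <- if (is.matrix(coeffs)) coeffs else matrix(coeffs, nrow = 1)
  if (!all(is.finite(x))) stop("assign_nearest: non-finite coefficients", call. = FALSE)
  if (ncol(x) != ncol(model$centroids)) {
    stop("assign_nearest: expected ", ncol(model$centroids),
         " coefficients, got ", ncol(x), call. = FALSE)
  }
  d2 <- .dist2(x, model$centroids)
  # relative round-off guard so equidistant centroids tie to the lowest id
  mins <- apply(d2, 1, min)
  tie <- d2 <= mins + pmax(1e-12, 1e-9 * mins)
  id <- max.col(tie, ties.method = "first") - 1L
  if (is.matrix(coeffs)) id else id[[1]]
}

#' Fit the multi-channel sort model
#'
#' The central fitting function: per-channel k-means models over the wavelet
#' feature matrix of a stream, bundled into one object that `predict` maps
#' to per-channel cluster assignments — the inputs of every downstream sort
#' decision.
#'
#' @param features wavelet feature matrix from [wavelet_features()] (columns
#'   `<channel>.c<i>`), or a `pulse_stream` (features are computed).
#' @param k clusters per channel: scalar or per-channel vector (1..8).
#' @param seed integer seed; channel c uses `seed + c - 1`.
#' @param channels channel names; inferred from column names by default.
#' @param ... passed to [fit_channel()].
#' @return An object of class `maps_model`: list of `channel_model`s plus the
#'   per-event assignment matrix of the training data.
#' @export
fit_sort_model <- function(features, k = 6L, seed = 1L, channels = NULL, ...) {
  if (inherits(features, "pulse_stream")) features <- wavelet_features(features)
  stopifnot(is.matrix(features))
  if (is.null(channels)) {
    channels <- unique(sub("\\.c[0-9]+$", "", colnames(features)))
  }
  if (length(k) == 1L) k <- rep(as.integer(k), length(channels))
  stopifnot(length(k) == length(channels))
  models <- vector("list", length(channels))
  names(models) <- channels
  assignment <- matrix(0L, nrow(features), length(channels),
                       dimnames = list(NULL, channels))
  for (i in seq_along(channels)) {
    cols <- grep(paste0("^", channels[i], "\\.c[0-9]+$"), colnames(features))
    if (!length(cols)) stop("no feature columns for channel ", channels[i], call. = FALSE)
    models[[i]] <- fit_channel(features[, cols, drop = FALSE], k = k[i],
                               seed = if (is.null(seed)) NULL else seed + i - 1L,
                               channel = channels[i], ...)
    assignment[, i] <- models[[i]]$assignment
  }
  structure(list(channels = models, k = k, assignment = assignment,
                 n_events = nrow(features), seed = seed),
            class = "maps_model")
}

#' @export
print.maps_model <- function(x, ...) {
  cat(sprintf("Multi-channel sort model: %d channels, %d training events\n",
              length(x$channels), x$n_events))
  for (m in x$channels) {
    cat(sprintf("  %-8s k = %d, inertia = %.4g\n", m$channel, m$k, m$inertia))
  }
  invisible(x)
}

#' @export
summary.maps_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$channels, function(m) {
    sizes <- tabulate(m$assignment + 1L, nbins = m$k)
    data.frame(channel = m$channel, cluster = 0:(m$k - 1), size = sizes,
               fraction = sizes / length(m$assignment))
  }))
  rownames(tab) <- NULL
  tab
}

#' Predict per-channel cluster assignments
#'
#' @param object a `maps_model`.
#' @param newdata wavelet feature matrix or `pulse_stream`; omitted, the
#'   training assignments are returned.
#' @param ... unused.
#' @return integer matrix, n x n_channels, of 0-based cluster ids.
#' @export
predict.maps_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignment)
  if (inherits(newdata, "pulse_stream")) newdata <- wavelet_features(newdata)
  out <- matrix(0L, nrow(newdata), length(object$channels),
                dimnames = list(NULL, names(object$channels)))
  for (i in seq_along(object$channels)) {
    m <- object$channels[[i]]
    cols <- grep(paste0("^", m$channel, "\\.c[0-9]+$"), colnames(newdata))
    if (!length(cols)) stop("no feature columns for channel ", m$channel, call. = FALSE)
    out[, i] <- assign_nearest(newdata[, cols, drop = FALSE], m)
  }
  out
}

#' 2-D projection of a channel's coefficient space
#'
#' QC figure showing events and centroids in two chosen coefficient
#' dimensions of one channel.
#'
#' @param x a `maps_model`.
#' @param features wavelet feature matrix used for the event dots.
#' @param channel channel name to display.
#' @param dims two coefficient indices (0-based) to project on.
#' @param ... passed to plot.
#' @export
plot.maps_model <- function(x, features, channel = names(x$channels)[1],
                            dims = c(1, 2), ...) {
  m <- x$channels[[channel]]
  cols <- grep(paste0("^", channel, "\\.c[0-9]+$"), colnames(features))
  xy <- features[, cols[dims + 1], drop = FALSE]
  a <- assign_nearest(features[, cols, drop = FALSE], m)
  graphics::plot(xy, col = a + 1L, pch = 16, cex = 0.5,
                 xlab = paste0(channel, " coefficient ", dims[1]),
                 ylab = paste0(channel, " coefficient ", dims[2]), ...)
  graphics::points(m$centroids[, dims + 1, drop = FALSE], pch = 3, cex = 2,
                   lwd = 2, col = seq_len(m$k))
  invisible(x)
}

#' Export / import centroid tables
#'
#' The exchange format fed to the signal-processing electronics: one row per
#' (channel, cluster) with the centroid coordinates. Written as
#' tab-separated text with 17 significant digits so that import reproduces
#' nearest-centroid assignments bit-identically.
#'
#' @param models a `maps_model` or list of `channel_model`s.
#' @return `export_centroids` returns a data.frame with columns `channel`,
#'   `cluster`, `c0..c<p-1>`.
#' @export
export_centroids <- function(models) {
  if (inherits(models, "maps_model")) models <- models$channels
  if (!length(models)) {
    return(data.frame(channel = character(0), cluster = integer(0)))
  }
  stopifnot(all(vapply(models, inherits, TRUE, "channel_model")))
  tab <- do.call(rbind, lapply(models, function(m) {
    p <- ncol(m$centroids)
    df <- data.frame(channel = m$channel, cluster = 0:(m$k - 1))
    coords <- as.data.frame(m$centroids)
    names(coords) <- paste0("c", 0:(p - 1))
    cbind(df, coords)
  }))
  rownames(tab) <- NULL
  if (anyDuplicated(tab[, c("channel", "cluster")])) {
    stop("export_centroids: duplicate (channel, cluster) keys", call. = FALSE)
  }
  tab
}

#' @rdname export_centroids
#' @param path file path for the tab-separated centroid table.
#' @export
write_centroids <- function(models, path) {
  tab <- export_centroids(models)
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "cluster"
  out <- tab
  out[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_centroids
#' @return `read_centroids` returns a named list of `channel_model`s (fit
#'   metadata absent; centroids only, sufficient for assignment).
#' @export
read_centroids <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("channel", "cluster")])) {
    stop("read_centroids: duplicate (channel, cluster) keys in ", path,
         call. = FALSE)
  }
  chans <- unique(tab$channel)
  models <- lapply(chans, function(ch) {
    rows <- tab[tab$channel == ch, , drop = FALSE]
    rows <- rows[order(rows$cluster), , drop = FALSE]
    if (!identical(rows$cluster, 0:(nrow(rows) - 1))) {
      stop("read_centroids: cluster ids of channel ", ch,
           " are not contiguous from 0", call. = FALSE)
    }
    cen <- as.matrix(rows[, grep("^c[0-9]+$", names(rows)), drop = FALSE])
    rownames(cen) <- as.character(rows$cluster)
    structure(list(channel = ch, k = nrow(cen), centroids = cen,
                   assignment = NULL, inertia = NA_real_,
                   iterations = NA_integer_, seed = NULL,
                   scaled = FALSE, scale_center = NULL, scale_sd = NULL),
              class = "channel_model")
  })
  names(models) <- chans
  models
}
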