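# Sort-cluster definition: conjunctions of single-channel clusters across
# channels, the enrichment statistic, and the two-ranking selection of sort
# clusters per reference population.

#' Sort cluster: a conjunction of single-channel clusters
#'
#' A sort criterion of the form "cluster i in channel A AND cluster j in
#' channel B (AND ...)", at most one cluster per channel. An event is sorted
#' only when its nearest-centroid assignment matches every part.
#'
#' @param parts named integer vector: names are channel ids, values 0-based
#'   single-channel cluster ids.
#' @param members optional 0-based event indices belonging to the cluster in
#'   a reference dataset.
#' @return An object of class `sort_cluster` with a canonical `name` like
#'   `"SSC:2&FSC4:0"`.
#' @export
sort_cluster <- function(parts, members = NULL) {
  stopifnot(length(parts) >= 1, !is.null(names(parts)),
            !anyDuplicated(names(parts)))
  parts <- vapply(parts, as.integer, integer(1))
  structure(list(parts = parts,
                 name = paste(sprintf("%s:%d", names(parts), parts),
                              collapse = "&"),
                 members = if (is.null(members)) NULL else
                   sort(unique(as.integer(members)))),
            class = "sort_cluster")
}

#' @export
print.sort_cluster <- function(x, ...) {
  cat(sprintf("Sort cluster %s (%s members)\n", x$name,
              if (is.null(x$members)) "unresolved" else length(x$members)))
  invisible(x)
}

#' Enumerate all cross-channel conjunction clusters
#'
#' Generates every conjunction (logical AND) of single-channel clusters from
#' `order` distinct channels: for each unordered channel set and each
#' combination of cluster ids, a [sort_cluster()] whose membership is the
#' intersection of the single-channel memberships.
#'
#' @param assignment n x n_channels integer matrix of 0-based cluster ids
#'   (e.g. from [predict.maps_model()]), columns named by channel.
#' @param k clusters per channel (scalar or per-channel vector); inferred
#'   from the assignment matrix when missing.
#' @param order number of channels per conjunction (default 2).
#' @return list of `sort_cluster` objects with resolved 0-based memberships
#'   (possibly empty memberships are retained).
#' @export
enumerate_conjunctions <- function(assignment, k = NULL, order = 2L) {
  stopifnot(is.matrix(assignment), !is.null(colnames(assignment)))
  chans <- colnames(assignment)
  order <- as.integer(order)
  if (order < 1L || order > length(chans)) {
    stop("order must lie in 1..", length(chans), call. = FALSE)
  }
  if (is.null(k)) k <- apply(assignment, 2, max) + 1L
  if (length(k) == 1L) k <- rep(as.integer(k), length(chans))
  out <- list()
  combos <- utils::combn(seq_along(chans), order, simplify = FALSE)
  for (set in combos) {
    ids <- do.call(expand.grid, lapply(set, function(j) 0:(k[j] - 1L)))
    for (r in seq_len(nrow(ids))) {
      want <- as.integer(ids[r, ])
      sel <- rep(TRUE, nrow(assignment))
      for (m in seq_along(set)) {
        sel <- sel & assignment[, set[m]] == want[m]
      }
      parts <- want
      names(parts) <- chans[set]
      out[[length(out) + 1L]] <- sort_cluster(parts, members = which(sel) - 1L)
    }
  }
  out
}

#' Enrichment of a cluster with a population
#'
#' The enrichment of cluster c with population P is the frequency of P
#' inside c relative to its frequency in the whole sample:
#' \deqn{x(P, c) = \frac{N(P, c) / N(\cdot, c)}{N(P, \cdot) / N(\cdot, \cdot)}}
#' where N(P, c) counts events of population P inside c and a dot sums over
#' the corresponding index. x = 1 means no enrichment; a cluster containing
#' only P reaches the maximum achievable value, the reciprocal of P's
#' prevalence ([max_achievable_enrichment()]).
#'
#' @param labels per-event population labels (all events of the sample).
#' @param members 0-based event indices of the cluster.
#' @return list with `x` (named per population; `NA` and `flagged = TRUE`
#'   when the cluster is empty), counts `N_Pc`, `N_c`, `N_P`, `N`, and
#'   `size_frac = N_c / N`.
#' @export
enrichment <- function(labels, members) {
  n <- length(labels)
  stopifnot(n > 0)
  members <- as.integer(members)
  if (length(members) && (min(members) < 0L || max(members) >= n)) {
    stop("enrichment: member index out of range", call. = FALSE)
  }
  pops <- sort(unique(labels))
  N_P <- vapply(pops, function(p) sum(labels == p), numeric(1))
  N_c <- length(members)
  in_c <- labels[members + 1L]
  N_Pc <- vapply(pops, function(p) sum(in_c == p), numeric(1))
  # cross-multiplied form: one exactly-rounded division of exact integer
  # products, so pure clusters hit 1/prevalence bit-exactly
  x <- if (N_c > 0) (N_Pc * n) / (N_c * N_P) else rep(NA_real_, length(pops))
  names(x) <- pops
  list(x = x, N_Pc = N_Pc, N_c = N_c, N_P = N_P, N = n,
       size_frac = N_c / n, flagged = N_c == 0)
}

#' Maximum achievable enrichment of a population
#'
#' The enrichment a perfectly pure cluster of population P would reach:
#' the reciprocal of P's prevalence, `N / N(P)`.
#'
#' @param labels per-event population labels.
#' @param P population name.
#' @return numeric scalar.
#' @export
max_achievable_enrichment <- function(labels, P) {
  np <- sum(labels == P)
  if (np == 0) stop("population '", P, "' absent from the sample", call. = FALSE)
  length(labels) / np
}

#' Enrichment table over candidate sort clusters
#'
#' One row per (cluster, population) with counts, enrichment and size
#' fraction; the table behind both rankings.
#'
#' @param labels per-event population labels.
#' @param clusters list of [sort_cluster()]s with resolved memberships.
#' @param singlets optional [index_list()] of singlet-gated events; adds a
#'   `size_frac_singlets` column (cluster size as a fraction of singlets).
#' @return data.frame of class `enrichment_table`.
#' @export
enrichment_table <- function(labels, clusters, singlets = NULL) {
  pops <- sort(unique(labels))
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    e <- enrichment(labels, cl$members)
    df <- data.frame(cluster = i, name = cl$name, population = pops,
                     N_Pc = as.numeric(e$N_Pc), N_c = e$N_c,
                     x = as.numeric(e$x), size_frac = e$size_frac,
                     stringsAsFactors = FALSE)
    if (!is.null(singlets)) {
      ns <- length(singlets$indices)
      df$size_frac_singlets <-
        if (ns > 0) length(intersect(cl$members, singlets$indices)) / ns
        else NA_real_
    }
    df
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Rank conjunction clusters and select sort clusters
#'
#' Two rankings are built per population: ranking A holds the `top_n`
#' clusters with the highest enrichment (ties broken toward larger
#' clusters); ranking B holds the clusters whose enrichment reaches
#' `threshold_frac` of the maximum achievable enrichment, ordered by size
#' descending. Highly enriched clusters can be tiny and thus unsuitable for
#' sorting (dilution, long sort times), so the selection prefers ranking-B
#' entries whose size reaches `min_size_frac`, then falls back to ranking A,
#' de-duplicating across the rankings, until `top_n` clusters per population
#' are chosen. Empty clusters (undefined enrichment) are never selected.
#'
#' @param labels per-event population labels.
#' @param clusters list of resolved [sort_cluster()]s
#'   (see [enumerate_conjunctions()]).
#' @param threshold_frac ranking-B threshold as a fraction of the maximum
#'   achievable enrichment (0.75 for fixed-cell workflows, 0.67 for live).
#' @param top_n sort clusters to select per population (default 3).
#' @param min_size_frac minimum cluster size as a fraction of all events for
#'   preferred (ranking-B) selection (default 0.01).
#' @param singlets optional singlet [index_list()], reported in the table.
#' @param populations populations to build rankings for; defaults to every
#'   label present. Other labels (e.g. ungated events) still count toward
#'   cluster sizes and the sample total in the enrichment statistic.
#' @return An object of class `sort_selection`: list with `selected` (named
#'   per population: list of rows with cluster index, name, x, size),
#'   `table` (the full [enrichment_table()]), `x_max` per population,
#'   `threshold_frac`, and `short` (populations with fewer than `top_n`
#'   eligible clusters, selection returned with a warning).
#' @export
rank_and_select <- function(labels, clusters, threshold_frac = 0.75,
                            top_n = 3L, min_size_frac = 0.01,
                            singlets = NULL, populations = NULL) {
  stopifnot(length(clusters) >= 1)
  tab <- enrichment_table(labels, clusters, singlets = singlets)
  pops <- if (is.null(populations)) sort(unique(labels)) else populations
  x_max <- vapply(pops, function(p) max_achievable_enrichment(labels, p),
                  numeric(1))
  selected <- list()
  short <- character(0)
  for (p in pops) {
    sub <- tab[tab$population == p & !is.na(tab$x), , drop = FALSE]
    # ranking A: top_n by enrichment, ties toward larger clusters
    rank_a <- sub[order(-sub$x, -sub$N_c), , drop = FALSE]
    rank_a <- utils::head(rank_a, top_n)
    # ranking B: above-threshold clusters by size descending
    rank_b <- sub[sub$x >= threshold_frac * x_max[[p]], , drop = FALSE]
    rank_b <- rank_b[order(-rank_b$N_c, -rank_b$x), , drop = FALSE]
    big_b <- rank_b[rank_b$size_frac >= min_size_frac, , drop = FALSE]
    pool <- rbind(big_b, rank_a, rank_b)
    pool <- pool[!duplicated(pool$cluster), , drop = FALSE]
    sel <- utils::head(pool, top_n)
    if (nrow(sel) < top_n) {
      short <- c(short, p)
      warning("population '", p, "': only ", nrow(sel),
              " eligible sort clusters (requested ", top_n, ")", call. = FALSE)
    }
    selected[[p]] <- sel
  }
  structure(list(selected = selected, table = tab, x_max = x_max,
                 threshold_frac = threshold_frac, top_n = top_n,
                 min_size_frac = min_size_frac, short = short),
            class = "sort_selection")
}

#' @export
print.sort_selection <- function(x, ...) {
  total <- sum(vapply(x$selected, nrow, integer(1)))
  cat(sprintf("Sort selection: %d clusters over %d populations (threshold %.0f%% of x_max)\n",
              total, length(x$selected), 100 * x$threshold_frac))
  for (p in names(x$selected)) {
    s <- x$selected[[p]]
    cat(sprintf("  %s (x_max = %.3g):\n", p, x$x_max[[p]]))
    for (r in seq_len(nrow(s))) {
      cat(sprintf("    %-24s x = %6.3f  size = %5.2f%%\n",
                  s$name[r], s$x[r], 100 * s$size_frac[r]))
    }
  }
  invisible(x)
}

#' Selected sort clusters of a selection
#'
#' @param selection a [rank_and_select()] result.
#' @param clusters the cluster list the selection was computed from.
#' @return named list (per population) of lists of `sort_cluster`s.
#' @export
selected_clusters <- function(selection, clusters) {
  stopifnot(inherits(selection, "sort_selection"))
  lapply(selection$selected, function(s) clusters[s$cluster])
}

#' Write an enrichment/selection table as delimited text
#'
#' Mirrors the sort-cluster overview layout: one column per selected sort
#' cluster, rows for each channel's contributing single-channel cluster id,
#' the size as a percentage of single cells (or of all events when no
#' singlet gate was supplied), and the assigned population.
#'
#' @param selection a [rank_and_select()] result.
#' @param clusters the cluster list the selection indexes into.
#' @param path output path (tab-separated).
#' @export
write_selection_table <- function(selection, clusters, path) {
  sel <- selected_clusters(selection, clusters)
  flat <- unlist(sel, recursive = FALSE)
  pops <- rep(names(sel), vapply(sel, length, integer(1)))
  chans <- unique(unlist(lapply(flat, function(cl) names(cl$parts))))
  rows <- lapply(chans, function(ch) {
    vapply(flat, function(cl) {
      if (ch %in% names(cl$parts)) as.character(cl$parts[[ch]]) else "-"
    }, character(1))
  })
  stats <- do.call(rbind, selection$selected)
  size_col <- if ("size_frac_singlets" %in% names(stats) &&
                  !anyNA(stats$size_frac_singlets)) {
    stats$size_frac_singlets
  } else stats$size_frac
  m <- rbind(do.call(rbind, rows),
             sprintf("%.2f", 100 * size_col),
             pops)
  dimnames(m) <- list(c(paste0(chans, " cluster"), "% of single cells", "Phase"),
                      paste("Sort cluster", seq_along(flat)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
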