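# Reference-label definition: rectangular 2-D gates on scalar features,
# singlet gating on width/area, merged multi-file datasets, and plain-text
# event-index files. Event indices are 0-based in all public index objects
# and on disk, matching the acquisition software's convention of numbering
# events from zero.

#' Rectangular 2-D gate
#'
#' @param x_feature,y_feature column names of the feature table.
#' @param x_min,x_max,y_min,y_max gate bounds; each interval is half-open,
#'   `min <= value < max`.
#' @return An object of class `rect_gate`.
#' @export
rect_gate <- function(x_feature, y_feature, x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop("rect_gate: min must be < max on both axes", call. = FALSE)
  }
  structure(list(x_feature = x_feature, y_feature = y_feature,
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "rect_gate")
}

#' Event index list
#'
#' A named, sorted, duplicate-free set of 0-based event indices — the unit of
#' exchange between gating software and the sort-preparation analysis.
#'
#' @param name gate or population name.
#' @param indices 0-based event indices.
#' @param n_events total number of events the indices refer to (optional,
#'   used for bounds checking).
#' @return An object of class `index_list`.
#' @export
index_list <- function(name, indices, n_events = NA_integer_) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && indices[1] < 0L) {
    stop("index_list: indices must be >= 0", call. = FALSE)
  }
  if (!is.na(n_events) && length(indices) && indices[length(indices)] >= n_events) {
    stop("index_list: index out of range [0, n_events)", call. = FALSE)
  }
  structure(list(name = as.character(name), indices = indices,
                 n_events = as.integer(n_events)),
            class = "index_list")
}

#' @export
print.index_list <- function(x, ...) {
  cat(sprintf("Index list '%s': %d events\n", x$name, length(x$indices)))
  invisible(x)
}

#' Apply a rectangular gate to a feature table
#'
#' @param features data.frame of per-event scalar features.
#' @param gate a [rect_gate()].
#' @param name name for the resulting index list (defaults to the gate axes).
#' @return An [index_list()] of the 0-based indices of events inside the gate
#'   (`x_min <= x < x_max` and `y_min <= y < y_max`).
#' @export
apply_gate <- function(features, gate, name = NULL) {
  stopifnot(inherits(gate, "rect_gate"), is.data.frame(features))
  for (f in c(gate$x_feature, gate$y_feature)) {
    if (!f %in% names(features)) {
      stop("apply_gate: unknown feature '", f, "'", call. = FALSE)
    }
  }
  x <- features[[gate$x_feature]]; y <- features[[gate$y_feature]]
  keep <- x >= gate$x_min & x < gate$x_max & y >= gate$y_min & y < gate$y_max
  if (is.null(name)) name <- paste0(gate$x_feature, "/", gate$y_feature)
  index_list(name, which(keep) - 1L, n_events = nrow(features))
}

#' Singlet gate on pulse width and area
#'
#' Doublets (two cells transiting back-to-back) show an inflated width at
#' similar height, so their area-to-width ratio falls below that of singlets.
#' Events are kept when `A/W` lies within `ratio_bounds` (closed interval);
#' events with `W = 0` are excluded, not errors.
#'
#' @param W per-event pulse widths (samples).
#' @param A per-event pulse areas (a.u. x samples).
#' @param ratio_bounds numeric length-2, inclusive bounds on A/W.
#' @param name name for the index list.
#' @return An [index_list()] of kept events (0-based).
#' @export
singlet_gate <- function(W, A, ratio_bounds, name = "singlets") {
  stopifnot(length(W) == length(A), length(ratio_bounds) == 2)
  ok <- W > 0
  r <- ifelse(ok, A / W, NA_real_)
  keep <- ok & r >= ratio_bounds[1] & r <= ratio_bounds[2]
  index_list(name, which(keep) - 1L, n_events = length(W))
}

#' Merge labelled per-file datasets into one event table
#'
#' Mirrors the workflow in which separately acquired datasets (one per
#' reference population) are concatenated into a single file whose `file_id`
#' column records each event's source. Order is preserved within each source;
#' sources are concatenated in the given order; event ids are re-assigned
#' 0-based over the merged table.
#'
#' @param datasets named list of data.frames with identical columns; names
#'   are the file labels.
#' @return data.frame with `event_id` (0-based) and `file_id` columns
#'   prepended to the shared feature columns.
#' @export
merge_labeled_files <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1, !is.null(names(datasets)))
  merged <- do.call(rbind, c(datasets, list(make.row.names = FALSE)))
  file_id <- rep(names(datasets), vapply(datasets, nrow, integer(1)))
  cbind(data.frame(event_id = seq_len(nrow(merged)) - 1L, file_id = file_id,
                   stringsAsFactors = FALSE),
        merged)
}

#' Write / read event-index files
#'
#' Plain text, one integer per line, LF line endings. `base` selects the
#' on-disk numbering convention (0- or 1-based); in-memory index lists are
#' always 0-based.
#'
#' @param il an [index_list()].
#' @param path file path.
#' @param base on-disk index base, 0 (default) or 1.
#' @return `read_index` returns an [index_list()] (named after the file).
#' @export
write_index <- function(il, path, base = 0L) {
  stopifnot(inherits(il, "index_list"), base %in% c(0L, 1L))
  con <- file(path, "wb")  # binary mode pins LF endings
  on.exit(close(con))
  writeLines(as.character(il$indices + as.integer(base)), con, sep = "\n")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path, base = 0L) {
  stopifnot(base %in% c(0L, 1L))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  v <- suppressWarnings(as.integer(lines))
  if (anyNA(v)) stop("read_index: non-integer line in ", path, call. = FALSE)
  index_list(sub("\\.[^.]*$", "", basename(path)), v - as.integer(base))
}
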