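# Observable layer: apparent diffusion coefficients, logarithmic histograms,
# track linking, and per-cell groupings.

#' Apparent diffusion coefficient of a short track
#'
#' For a track of L+1 localisations, the mean squared frame-to-frame
#' displacement in the image plane divided by 4 times the frame interval:
#' \deqn{D^* = \frac{1}{L} \sum_{i=1}^{L} \lVert r_{i+1} - r_i \rVert^2 / (4 \Delta t).}
#' Localisation error inflates the estimate by \eqn{\sigma^2/\Delta t}
#' (0.1225 um^2/s for sigma = 0.035 um at 10 ms framing); this is a property
#' of the observable, deliberately not corrected for, since the forward model
#' convolutes the same error.
#'
#' @param track data frame with columns `x`, `y` (um) and `frame`, strictly
#'   increasing consecutive frames; 2 to 9 rows.
#' @param frame_interval frame interval (s).
#' @return Apparent diffusion coefficient (um^2/s).
#' @examples
#' tr <- data.frame(x = c(0, 0.1), y = c(0, 0), frame = 1:2)
#' estimate_dstar(tr, 0.010)  # 0.25
#' @export
estimate_dstar <- function(track, frame_interval) {
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 localisations for D* estimation")
  if (n > 9) stop("tracks longer than 9 localisations are discarded, not estimated")
  if (any(diff(track$frame) != 1)) {
    stop("track frames must be strictly increasing and consecutive")
  }
  L <- n - 1
  sum(diff(track$x)^2 + diff(track$y)^2) / L / (4 * frame_interval)
}

#' Logarithmic histogram of apparent diffusion coefficients
#'
#' Collects D* values into `hist_bins` logarithmically spaced bins over
#' `[hist_min, hist_max]` (default 85 bins over 0.04-10 um^2/s). Values
#' outside the range are clamped into the edge bins, so counts always sum to
#' the number of inputs and fitted and empirical histograms share a common
#' normalisation.
#'
#' @param dstars numeric vector of apparent diffusion coefficients (um^2/s).
#' @param imaging an [imaging_config()].
#' @return A `diff_histogram`: list with `bin_edges` (length bins+1),
#'   `counts`, `n_tracks`.
#' @export
build_histogram <- function(dstars, imaging) {
  edges <- histogram_edges(imaging)
  nb <- imaging$hist_bins
  dstars <- dstars[!is.na(dstars)]
  clamped <- pmin(pmax(dstars, edges[1]), edges[nb + 1])
  idx <- findInterval(clamped, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, counts = counts, n_tracks = length(dstars)),
            class = "diff_histogram")
}

histogram_edges <- function(imaging) {
  10^seq(log10(imaging$hist_min), log10(imaging$hist_max),
         length.out = imaging$hist_bins + 1)
}

#' Bin centres (geometric means of edges) of a diffusion histogram
#' @param hist a `diff_histogram`.
#' @return Numeric vector of bin centres (um^2/s).
#' @export
histogram_centers <- function(hist) {
  e <- hist$bin_edges
  sqrt(e[-length(e)] * e[-1])
}

#' @export
print.diff_histogram <- function(x, ...) {
  cat(sprintf("diff_histogram: %d tracks in %d log bins over [%.3g, %.3g] um^2/s\n",
              x$n_tracks, length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Write / read a diffusion histogram as two-column CSV
#' @param hist a `diff_histogram`.
#' @param path file path.
#' @return The path (write) or a `diff_histogram` (read). Reading recovers
#'   the bin edges from the stored centres assuming logarithmic spacing.
#' @export
write_histogram <- function(hist, path) {
  write.csv(data.frame(bin_center = histogram_centers(hist),
                       count = hist$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("bin_center", "count") %in% names(df)))
  ctr <- df$bin_center
  lr <- log10(ctr)
  step <- diff(lr)
  if (max(abs(step - step[1])) > 1e-6) {
    stop("bin centres are not logarithmically spaced")
  }
  edges <- 10^c(lr - step[1] / 2, lr[length(lr)] + step[1] / 2)
  structure(list(bin_edges = edges, counts = as.integer(df$count),
                 n_tracks = sum(df$count)),
            class = "diff_histogram")
}

#' Link localisations into tracks
#'
#' Greedy nearest-neighbour linking between consecutive frames within each
#' cell: candidate pairs with displacement at most `max_jump` are assigned in
#' order of increasing displacement (ties in ambiguous conflicts thus resolve
#' toward the minimum total displacement); there is no gap closing. Tracks
#' acquiring more than 9 localisations are discarded.
#'
#' @param table localisation data frame with columns `frame`, `x`, `y` (um)
#'   and optionally `cell_id` (default one cell).
#' @param max_jump maximum per-step displacement (um); default 0.8, about 5
#'   standard deviations of the fastest expected frame displacement.
#' @param frame_interval frame interval (s), stored for downstream use.
#' @return A `track_set` with per-track D* in `info`.
#' @export
link_localisations <- function(table, max_jump = 0.8, frame_interval = 0.010) {
  stopifnot(all(c("frame", "x", "y") %in% names(table)))
  if (is.null(table$cell_id)) table$cell_id <- 1L
  if (anyDuplicated(table[, c("frame", "x", "y", "cell_id")])) {
    stop("duplicate (frame, position) rows in localisation table")
  }
  table <- table[order(table$cell_id, table$frame), , drop = FALSE]
  loc_track <- integer(nrow(table))
  next_id <- 1L
  for (cell in unique(table$cell_id)) {
    rows <- which(table$cell_id == cell)
    frames <- table$frame[rows]
    open_rows <- integer(0)      # row index of last localisation of open tracks
    for (f in sort(unique(frames))) {
      cur <- rows[frames == f]
      prev <- open_rows[table$frame[open_rows] == f - 1L]
      assigned_cur <- rep(FALSE, length(cur))
      used_prev <- rep(FALSE, length(prev))
      if (length(prev) && length(cur)) {
        dx <- outer(table$x[prev], table$x[cur], "-")
        dy <- outer(table$y[prev], table$y[cur], "-")
        dist <- sqrt(dx^2 + dy^2)
        cand <- which(dist <= max_jump, arr.ind = TRUE)
        if (nrow(cand)) {
          cand <- cand[order(dist[cand]), , drop = FALSE]
          for (k in seq_len(nrow(cand))) {
            i <- cand[k, 1]; j <- cand[k, 2]
            if (!used_prev[i] && !assigned_cur[j]) {
              loc_track[cur[j]] <- loc_track[prev[i]]
              used_prev[i] <- TRUE
              assigned_cur[j] <- TRUE
            }
          }
        }
      }
      for (j in which(!assigned_cur)) {
        loc_track[cur[j]] <- next_id
        next_id <- next_id + 1L
      }
      open_rows <- cur
    }
  }
  table$track <- loc_track
  sizes <- table(loc_track)
  keep <- as.integer(names(sizes)[sizes <= 9])
  table <- table[table$track %in% keep, , drop = FALSE]
  imaging0 <- imaging_config(frame_interval = frame_interval)
  if (!nrow(table)) return(empty_track_set(imaging0))
  ids <- sort(unique(table$track))
  table$track <- match(table$track, ids)
  table <- table[order(table$track, table$frame), , drop = FALSE]
  info <- do.call(rbind, lapply(split(table, factor(table$track, levels = seq_along(ids))),
                                function(tr) {
    d <- if (nrow(tr) >= 2) {
      sum(diff(tr$x)^2 + diff(tr$y)^2) / (nrow(tr) - 1) / (4 * frame_interval)
    } else NA_real_
    data.frame(track = tr$track[1], length = nrow(tr) - 1L,
               cell_id = tr$cell_id[1], dstar = d)
  }))
  rownames(info) <- NULL
  imaging <- imaging_config(frame_interval = frame_interval)
  new_track_set(table[, c("track", "frame", "x", "y", "cell_id")], info, imaging)
}

#' Group cells by their track counts
#'
#' Assigns each cell to the unique integer range containing its track count;
#' cells outside all ranges are excluded and reported in the `excluded`
#' attribute. Default ranges follow the copy-number analysis: 7-50, 51-100,
#' 101-150, 151-200 tracks.
#'
#' @param ts a `track_set` whose `info` has a `cell_id` column.
#' @param ranges list of inclusive integer ranges `c(lo, hi)`.
#' @return Named list of `track_set` objects, one per non-empty range, with
#'   attribute `excluded` (cell ids outside all ranges).
#' @export
group_cells_by_track_count <- function(ts,
                                       ranges = list(c(7, 50), c(51, 100),
                                                     c(101, 150), c(151, 200))) {
  stopifnot(!is.null(ts$info$cell_id))
  bounds <- do.call(rbind, ranges)
  if (nrow(bounds) > 1) {
    ord <- order(bounds[, 1])
    b <- bounds[ord, , drop = FALSE]
    if (any(b[-1, 1] <= b[-nrow(b), 2])) stop("overlapping ranges")
  }
  counts <- table(ts$info$cell_id)
  labels <- sprintf("%d-%d", bounds[, 1], bounds[, 2])
  assign_range <- function(n) {
    hit <- which(n >= bounds[, 1] & n <= bounds[, 2])
    if (length(hit) == 1) hit else NA_integer_
  }
  cell_range <- vapply(as.integer(counts), assign_range, integer(1))
  names(cell_range) <- names(counts)
  excluded <- names(counts)[is.na(cell_range)]
  out <- list()
  for (g in seq_along(ranges)) {
    cells <- names(cell_range)[!is.na(cell_range) & cell_range == g]
    if (!length(cells)) next
    keep <- ts$info$cell_id %in% cells
    locs <- if (!is.null(ts$locs)) {
      ts$locs[ts$locs$cell_id %in% cells, , drop = FALSE]
    } else NULL
    out[[labels[g]]] <- new_track_set(locs, ts$info[keep, , drop = FALSE],
                                      attr(ts, "imaging"))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Mean apparent diffusion coefficient by track length
#'
#' Lengths 3 to 7 steps are reported individually; 8 steps and longer are
#' pooled into a `">=8"` class. Empty classes are omitted.
#'
#' @param ts a `track_set` with per-track `length` and `dstar` in `info`.
#' @return Data frame with columns `length`, `n`, `mean_dstar`, `se`.
#' @export
mean_dstar_by_length <- function(ts) {
  info <- ts$info[!is.na(ts$info$dstar), , drop = FALSE]
  cls <- ifelse(info$length >= 8, ">=8", as.character(info$length))
  keep <- cls %in% c("3", "4", "5", "6", "7", ">=8")
  info <- info[keep, , drop = FALSE]; cls <- cls[keep]
  if (!nrow(info)) {
    return(data.frame(length = character(), n = integer(),
                      mean_dstar = numeric(), se = numeric()))
  }
  lev <- c("3", "4", "5", "6", "7", ">=8")
  out <- do.call(rbind, lapply(lev[lev %in% cls], function(l) {
    d <- info$dstar[cls == l]
    data.frame(length = l, n = length(d), mean_dstar = mean(d),
               se = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Per-track apparent diffusion coefficients of a track set
#'
#' Convenience accessor: per-track `dstar` values as stored in `info` (for
#' simulated sets, computed from the noisy localisations during simulation;
#' for linked sets, computed at link time).
#'
#' @param ts a `track_set`.
#' @param min_steps drop tracks shorter than this many steps (default 1).
#' @return Numeric vector of D* values.
#' @export
track_dstars <- function(ts, min_steps = 1) {
  reps <- attr(ts, "dstar_reps")
  if (!is.null(reps)) {
    nr <- length(reps) / nrow(ts$info)
    keep <- rep(!is.na(ts$info$dstar) & ts$info$length >= min_steps,
                each = nr)
    return(reps[keep])
  }
  ts$info$dstar[!is.na(ts$info$dstar) & ts$info$length >= min_steps]
}
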