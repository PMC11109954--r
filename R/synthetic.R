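# Synthetic experiments: complete localisation tables with cell assignments
# and known ground truth, so every downstream stage is testable without any
# experimental download.

#' Generate a complete synthetic sptPALM experiment
#'
#' Emulates the heterogeneous expression of a cell population: each cell
#' draws a track count from `track_count_law` (default log-uniform on
#' 7 to 200, covering the copy-number ranges of the grouping analysis), then
#' simulates that many tracks with the forward model ([simulate_ensemble()],
#' or the two-species mixture when `bound_fraction > 0`). Tracks of a cell
#' are assigned disjoint frame windows (sparse photoactivation: one emitter
#' at a time), so linking is well-posed. Fully reproducible from `seed`.
#'
#' @param rates a [kinetic_rates()].
#' @param diffs a [state_diffusion()].
#' @param imaging an [imaging_config()].
#' @param geometry a [cell_geometry()].
#' @param n_cells number of cells.
#' @param track_count_law function(n) returning n positive integer track
#'   counts; default log-uniform on \[7, 200\].
#' @param bound_fraction per-particle probability of the target-bound
#'   species.
#' @param seed integer root seed.
#' @return A `synthetic_experiment`: list with `table` (localisation data
#'   frame: `frame`, `x`, `y` (um), `uncertainty` (um), `cell_id`,
#'   `track_id`), `tracks` (the generating `track_set`), `cells` (roster:
#'   `cell_id`, `track_count`), and `truth` (rates, bound_fraction, seed,
#'   per-track species).
#' @export
generate_experiment <- function(rates, diffs, imaging, geometry,
                                n_cells = 100,
                                track_count_law = NULL,
                                bound_fraction = 0, seed = 1) {
  if (is.null(track_count_law)) {
    track_count_law <- function(n) {
      floor(exp(runif(n, log(7), log(201))))
    }
  }
  counts <- with_seed(seed, {
    n <- track_count_law(n_cells)
    stopifnot(all(n >= 1), all(n == floor(n)))
    as.integer(n)
  })
  total <- sum(counts)
  ts <- simulate_mixture_ensemble(total, bound_fraction, rates, diffs,
                                  imaging, geometry, seed = seed,
                                  keep_locs = TRUE)
  cell_of_track <- rep.int(seq_len(n_cells), counts)
  ts$info$cell_id <- cell_of_track
  ts$locs$cell_id <- cell_of_track[ts$locs$track]
  # stagger tracks of a cell into disjoint frame windows (2-frame dark gap)
  track_len <- ts$info$length
  offset <- integer(total)
  pos <- 1L
  for (cell in seq_len(n_cells)) {
    idx <- which(cell_of_track == cell)
    start <- 0L
    for (i in idx) {
      offset[i] <- start
      start <- start + track_len[i] + 3L
    }
  }
  ts$locs$frame <- ts$locs$frame + offset[ts$locs$track]
  table <- data.frame(frame = ts$locs$frame, x = ts$locs$x, y = ts$locs$y,
                      uncertainty = imaging$sigma_loc,
                      cell_id = ts$locs$cell_id, track_id = ts$locs$track)
  structure(list(
    table = table,
    tracks = ts,
    cells = data.frame(cell_id = seq_len(n_cells), track_count = counts),
    truth = list(rates = rates, bound_fraction = bound_fraction, seed = seed,
                 species = ts$info$species)),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic_experiment: %d cells, %d tracks, %d localisations (seed %s)\n",
              nrow(x$cells), nrow(x$tracks$info), nrow(x$table),
              format(x$truth$seed)))
  invisible(x)
}

#' Write / read localisation tables (ThunderSTORM-like CSV dialect)
#'
#' On disk, positions and uncertainties are in nanometres under the headers
#' `frame, x [nm], y [nm], uncertainty [nm], cell_id, track_id`; in memory
#' they are micrometres. Values are stored with 0.01 nm precision, so a
#' write/read round trip is lossless to that precision.
#'
#' @param experiment a `synthetic_experiment` or a localisation data frame
#'   with the in-memory columns of [generate_experiment()].
#' @param path file path.
#' @return `write_localisations()`: the path, invisibly.
#' @export
write_localisations <- function(experiment, path) {
  table <- if (inherits(experiment, "synthetic_experiment")) {
    experiment$table
  } else experiment
  stopifnot(all(c("frame", "x", "y", "uncertainty", "cell_id", "track_id")
                %in% names(table)))
  out <- data.frame(frame = table$frame,
                    x = round(table$x * 1000, 2),
                    y = round(table$y * 1000, 2),
                    uncertainty = round(table$uncertainty * 1000, 2),
                    cell_id = table$cell_id,
                    track_id = table$track_id)
  names(out) <- c("frame", "x [nm]", "y [nm]", "uncertainty [nm]",
                  "cell_id", "track_id")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localisations
#' @return `read_localisations()`: a localisation data frame (`frame`, `x`,
#'   `y`, `uncertainty` in um, `cell_id`, `track_id`).
#' @export
read_localisations <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  expected <- c("frame", "x [nm]", "y [nm]", "uncertainty [nm]",
                "cell_id", "track_id")
  if (length(header) == 0 || !all(expected %in% header)) {
    missing <- setdiff(expected, header)
    stop("missing header column(s): ", paste(missing, collapse = ", "))
  }
  df <- read.csv(path, check.names = FALSE)
  out <- data.frame(frame = as.integer(df[["frame"]]),
                    x = df[["x [nm]"]] / 1000,
                    y = df[["y [nm]"]] / 1000,
                    uncertainty = df[["uncertainty [nm]"]] / 1000,
                    cell_id = df[["cell_id"]],
                    track_id = df[["track_id"]])
  for (id in unique(out$track_id)) {
    fr <- out$frame[out$track_id == id]
    if (any(diff(fr) <= 0)) {
      stop("non-monotone frames within track id ", id)
    }
  }
  out
}

#' Rate-recovery benchmark over a grid of ground truths
#'
#' For each ground-truth rate set: generate a synthetic experiment, re-link
#' its localisations, estimate per-track D*, build the histogram, fit the
#' rates (initialised at `init_factor` times the truth), and bootstrap a
#' 95% interval for t_NTI. Reports relative errors and interval coverage.
#'
#' @param rate_grid list of [kinetic_rates()] ground truths.
#' @param n_tracks approximate number of tracks per experiment.
#' @param seed integer root seed.
#' @param diffs,imaging,geometry forward-model configuration.
#' @param config a [fit_config()] for the refits.
#' @param n_boot bootstrap replicates per experiment.
#' @param init_factor starting point = truth scaled by this factor.
#' @param relink re-link localisations from the table (full pipeline) or use
#'   the generator's ground-truth tracks directly (faster).
#' @return Data frame, one row per truth: fitted rates, `t_nti_true`,
#'   `t_nti_hat`, `t_nti_rel_err`, bootstrap interval, `covered`.
#' @export
recovery_suite <- function(rate_grid, n_tracks = 50000, seed = 1,
                           diffs = state_diffusion(),
                           imaging = imaging_config(),
                           geometry = cell_geometry(),
                           config = fit_config(), n_boot = 10,
                           init_factor = 2, relink = TRUE) {
  rows <- lapply(seq_along(rate_grid), function(i) {
    truth <- rate_grid[[i]]
    n_cells <- max(1L, ceiling(n_tracks / 57))  # E[log-unif 7..200] ~ 57
    expt <- generate_experiment(truth, diffs, imaging, geometry,
                                n_cells = n_cells, seed = seed + 1000 * i)
    ts <- if (relink) {
      link_localisations(expt$table, frame_interval = imaging$frame_interval)
    } else expt$tracks
    h <- build_histogram(track_dstars(ts), imaging)
    init <- kinetic_rates(truth[[1]] * init_factor, truth[[2]] * init_factor,
                          truth[[3]] * init_factor, truth[[4]] * init_factor)
    cfg_i <- config
    cfg_i$seed <- config$seed + 7000 * i   # independent forward realisations
    fit <- fit_rates(h, init, diffs, imaging, geometry, cfg_i)
    boot <- bootstrap_ci(ts, fit, diffs, imaging, geometry, cfg_i,
                         n_boot = n_boot, seed = seed + i)
    tn_true <- t_nti(truth); tn_hat <- t_nti(fit$rates)
    k <- as.numeric(fit$rates)
    data.frame(truth_id = i,
               k_3D_to_1D = k[1], k_1D_to_3D = k[2], k_1D_to_PAM = k[3],
               k_PAM_to_1D = k[4],
               converged = fit$converged,
               n_tracks = h$n_tracks,
               t_nti_true = tn_true, t_nti_hat = tn_hat,
               t_nti_rel_err = abs(tn_hat - tn_true) / tn_true,
               t_nti_lo = boot$t_nti_ci[1], t_nti_hi = boot$t_nti_ci[2],
               covered = tn_true >= boot$t_nti_ci[1] &
                         tn_true <= boot$t_nti_ci[2],
               boot_failed = boot$n_failed)
  })
  do.call(rbind, rows)
}
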