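# Forward Monte-Carlo simulator: localisation tracks from the state model
# inside a confined cell. The particle loop lives in src/sim.cpp; the R layer
# owns sampling laws, validation, and the track_set container.

#' State-change time of a competing-exponential transition
#'
#' Inverse-CDF draw of the exponential sojourn time, \eqn{-\ln(u)/k}. A zero
#' exit rate yields `Inf`: the state is never left.
#'
#' @param total_exit_rate sum of the exit rates of the current state (s^-1).
#' @param u uniform variate in (0, 1].
#' @return Time in seconds.
#' @examples
#' draw_state_change_time(100, exp(-1))  # 0.01 s
#' @export
draw_state_change_time <- function(total_exit_rate, u) {
  stopifnot(total_exit_rate >= 0)
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  if (total_exit_rate == 0) return(rep(Inf, length(u)))
  -log(u) / total_exit_rate
}

# Solve for q in p(L) ~ q^L on {lo..hi} such that the mean equals `target`.
track_length_q <- function(target, lo, hi) {
  stopifnot(lo >= 1, hi >= lo)
  if (target < lo || target > hi) {
    stop("infeasible mean track length: must lie in [min, max]")
  }
  if (lo == hi || target == lo) return(0)
  if (target == hi) return(Inf)
  mean_q <- function(lq) {
    w <- exp(lq * (lo:hi))
    sum((lo:hi) * w) / sum(w)
  }
  lq <- stats::uniroot(function(lq) mean_q(lq) - target,
                       lower = -50, upper = 50, tol = 1e-12)$root
  exp(lq)
}

#' Sample a track length from the truncated exponential law
#'
#' Track lengths follow an exponentially decaying law \eqn{p(L) \propto q^L}
#' on `{min_track_steps, ..., max_track_steps}` with the decay calibrated
#' numerically so the truncated mean equals `mean_track_steps` (default: mean
#' 3 steps on 1..8, emulating photoactivatable-fluorophore bleaching).
#'
#' @param imaging an [imaging_config()].
#' @param u uniform variate(s) in (0, 1].
#' @return Integer step count(s) in `[min_track_steps, max_track_steps]`.
#' @export
sample_track_length <- function(imaging, u) {
  lo <- imaging$min_track_steps; hi <- imaging$max_track_steps
  q <- track_length_q(imaging$mean_track_steps, lo, hi)
  if (q == 0) return(rep.int(lo, length(u)))
  if (!is.finite(q)) return(rep.int(hi, length(u)))
  w <- q^(seq(lo, hi) - lo)
  cdf <- cumsum(w / sum(w))
  lo + findInterval(u, cdf, left.open = TRUE)
}

#' Sample the initial state of a searching particle
#'
#' Draws from the stationary distribution of the linear three-state chain
#' (see [steady_state_fractions()]), the paper-mode initialisation of
#' simulated particles.
#'
#' @param rates a [kinetic_rates()].
#' @param u uniform variate(s) in (0, 1].
#' @return Character state label(s): `"3D"`, `"1D"` or `"PAM"`.
#' @export
initial_state <- function(rates, u) {
  f <- steady_state_fractions(rates)
  cdf <- cumsum(f)
  c("3D", "1D", "PAM")[1 + findInterval(u, cdf, left.open = TRUE)]
}

#' Propagate a particle position by one diffusion sub-step
#'
#' Displaces each coordinate by \eqn{\sqrt{2 D \, dt} \cdot z} and reflects
#' specularly at the spherocylinder wall.
#'
#' @param position numeric 3-vector (um), inside the geometry.
#' @param D diffusion coefficient of the current state (um^2/s).
#' @param geometry a [cell_geometry()].
#' @param dt time step (s).
#' @param gaussians 3 standard-normal variates.
#' @return New position (3-vector, inside the geometry).
#' @export
propagate_position <- function(position, D, geometry, dt, gaussians) {
  stopifnot(dt > 0, length(position) == 3, length(gaussians) == 3, D >= 0)
  pos <- position + sqrt(2 * D * dt) * gaussians
  reflect_spherocylinder(pos, geometry)
}

# R-side mirror of the C++ reflection, for testing and propagate_position.
reflect_spherocylinder <- function(pos, geometry) {
  h <- geometry$cylinder_length / 2; r <- geometry$radius
  for (i in 1:16) {
    x <- pos[1]; y <- pos[2]; z <- pos[3]
    if (abs(x) <= h) {
      rho <- sqrt(y^2 + z^2)
      if (rho <= r) return(pos)
      f <- (2 * r - rho) / rho
      pos <- c(x, y * f, z * f)
    } else {
      cx <- sign(x) * h
      d <- sqrt((x - cx)^2 + y^2 + z^2)
      if (d <= r) return(pos)
      f <- (2 * r - d) / d
      pos <- c(cx + (x - cx) * f, y * f, z * f)
    }
  }
  pos * (0.999 * r / sqrt(sum(pos^2)))
}

# Is a point inside the spherocylinder?
inside_spherocylinder <- function(pos, geometry) {
  h <- geometry$cylinder_length / 2; r <- geometry$radius
  x <- pos[1]
  if (abs(x) <= h) return(pos[2]^2 + pos[3]^2 <= r^2)
  (abs(x) - h)^2 + pos[2]^2 + pos[3]^2 <= r^2
}

#' Simulate an ensemble of localisation tracks
#'
#' Forward model of the sptPALM experiment: `n_particles` independent
#' particles are initialised uniformly in the cell and in the stationary
#' state mixture, advanced on the `t_step` grid with state switching and
#' confined Brownian motion, and observed — after the equilibration burn-in —
#' as planar (x, y) localisations with independent Gaussian error of
#' `sigma_loc` per coordinate, one per `frame_interval`, for a track length
#' drawn from the truncated exponential law.
#'
#' Each particle consumes an independent RNG stream derived from `seed`, so
#' results are reproducible and independent of particle order, and repeated
#' calls with the same seed reuse identical random numbers (the common
#' random numbers that make the fitting objective deterministic).
#'
#' @param n_particles number of particles (tracks).
#' @param rates a [kinetic_rates()].
#' @param diffs a [state_diffusion()].
#' @param imaging an [imaging_config()].
#' @param geometry a [cell_geometry()].
#' @param seed integer root seed.
#' @param keep_locs keep per-localisation coordinates (`TRUE`) or only
#'   per-track summaries (`FALSE`, faster; enough for histogram fitting).
#' @param noise_reps localisation-noise draws per path (see
#'   [simulate_mixture_ensemble()]).
#' @return A `track_set`: list with `locs` (data frame `track`, `frame`,
#'   `x`, `y`, `cell_id`; present when `keep_locs`), `info` (per-track
#'   `track`, `length`, `species`, `init_state`, `dstar`), and the generating
#'   configuration in attributes.
#' @export
simulate_ensemble <- function(n_particles, rates, diffs, imaging, geometry,
                              seed, keep_locs = TRUE, noise_reps = 1) {
  simulate_mixture_ensemble(n_particles, 0, rates, diffs, imaging, geometry,
                            seed, keep_locs = keep_locs,
                            noise_reps = noise_reps)
}

#' Simulate a two-species mixture of bound and searching particles
#'
#' Each particle is, with probability `bound_fraction`, a target-bound
#' particle diffusing with `D_Target` in a single static state; otherwise it
#' is a three-state searcher as in [simulate_ensemble()]. Species labels are
#' retained as ground truth in the `info` table.
#'
#' @inheritParams simulate_ensemble
#' @param bound_fraction probability of the target-bound species.
#' @param noise_reps number of independent localisation-noise draws per
#'   simulated path (conditional Monte Carlo). With `noise_reps > 1` each
#'   path contributes several apparent-D* values re-convolved with fresh
#'   noise, averaging out the localisation-noise component of the histogram
#'   variance at negligible cost; used by the fitting forward model.
#' @return A `track_set` (see [simulate_ensemble()]).
#' @export
simulate_mixture_ensemble <- function(n_particles, bound_fraction, rates,
                                      diffs, imaging, geometry, seed,
                                      keep_locs = TRUE, noise_reps = 1) {
  stopifnot(n_particles >= 0, bound_fraction >= 0, bound_fraction <= 1)
  validate_config(rates, diffs, imaging)
  if (n_particles == 0) return(empty_track_set(imaging))
  f <- steady_state_fractions(rates)
  q <- track_length_q(imaging$mean_track_steps, imaging$min_track_steps,
                      imaging$max_track_steps)
  q <- min(q, 1e6)  # mean at the upper support edge: all mass on max length
  raw <- .sim_tracks_cpp(
    as.integer(n_particles),
    as.numeric(rates)[1:4], as.numeric(diffs),
    bound_fraction, as.numeric(f),
    q, as.integer(imaging$min_track_steps),
    as.integer(imaging$max_track_steps),
    geometry$cylinder_length, geometry$radius,
    imaging$frame_interval, imaging$t_step,
    imaging$sigma_loc, imaging$equilibration,
    as.numeric(seed), keep_locs, as.integer(noise_reps))
  first_rep <- raw$dstar[seq(1, length(raw$dstar), by = noise_reps)]
  info <- data.frame(track = seq_len(n_particles), length = raw$length,
                     species = ifelse(raw$species == 1, "bound", "searching"),
                     init_state = c("3D", "1D", "PAM", "Target")[raw$init_state + 1],
                     dstar = first_rep)
  locs <- if (keep_locs) {
    data.frame(track = raw$track, frame = raw$frame, x = raw$x, y = raw$y,
               cell_id = 1L)
  } else NULL
  ts <- new_track_set(locs, info, imaging, seed = seed)
  if (noise_reps > 1) attr(ts, "dstar_reps") <- raw$dstar
  ts
}

#' Simulate a single localisation track
#'
#' Convenience wrapper around [simulate_ensemble()] for one particle: the
#' particle is initialised uniformly in the cell and in the stationary
#' state mixture, advanced on the sub-step grid, and observed as planar
#' localisations with Gaussian error after the burn-in.
#'
#' @inheritParams simulate_ensemble
#' @return Data frame with columns `x`, `y` (um) and `frame`, suitable for
#'   [estimate_dstar()].
#' @export
simulate_particle_track <- function(rates, diffs, imaging, geometry, seed) {
  ts <- simulate_ensemble(1, rates, diffs, imaging, geometry, seed)
  ts$locs[, c("x", "y", "frame")]
}

# track_set container ---------------------------------------------------------

new_track_set <- function(locs, info, imaging, seed = NULL) {
  structure(list(locs = locs, info = info),
            imaging = imaging, seed = seed, class = "track_set")
}

empty_track_set <- function(imaging) {
  new_track_set(
    data.frame(track = integer(), frame = integer(), x = numeric(),
               y = numeric(), cell_id = integer()),
    data.frame(track = integer(), length = integer(), species = character(),
               init_state = character(), dstar = numeric()),
    imaging)
}

#' Number of tracks in a track set
#' @param ts a `track_set`.
#' @return Integer count.
#' @export
n_tracks <- function(ts) nrow(ts$info)

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks", n_tracks(x)))
  if (!is.null(x$locs)) cat(sprintf(", %d localisations", nrow(x$locs)))
  if (nrow(x$info) && "species" %in% names(x$info)) {
    nb <- sum(x$info$species == "bound")
    if (nb > 0) cat(sprintf(" (%d bound)", nb))
  }
  cat("\n")
  invisible(x)
}

#' Time-weighted state occupancy of a long grid-stepped simulation
#'
#' Runs a single particle of the forward model (state dynamics only) for
#' `t_total` seconds on the `t_step` grid and reports the fraction of time
#' spent in each state. Serves as the simulation-side check of
#' [steady_state_fractions()].
#'
#' @param rates a [kinetic_rates()].
#' @param t_total total simulated time (s).
#' @param t_step grid step (s).
#' @param seed integer seed.
#' @return Named fractions `c(f_3D, f_1D, f_PAM)`.
#' @export
simulate_occupancy <- function(rates, t_total = 1000, t_step = 1e-4, seed = 1) {
  f <- steady_state_fractions(rates)
  out <- .occupancy_cpp(as.numeric(rates)[1:4], as.numeric(f), t_total,
                        t_step, as.numeric(seed))
  c(f_3D = out[1], f_1D = out[2], f_PAM = out[3])
}
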