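# MC-DDA fitting: recover kinetic rates from diffusion histograms via the
# stochastic forward model, with bootstrap confidence intervals; recover
# target-bound fractions via the two-species mixture.
#
# The objective is deterministic in the parameters (common random numbers:
# per-particle RNG streams derived from a frozen seed), and its Monte-Carlo
# variance is reduced by conditional averaging over the localisation noise
# (`noise_reps`). The search runs in a composite log parametrisation
# (log k_3D->1D, log t_NTI, log k_1D->PAM/k_PAM->1D, log k_PAM->1D) that is
# bijective with the four rates and aligns the best-identified direction
# (the non-target interaction time) with one axis: a Nelder-Mead pre-stage
# navigates the sloppy valley, and Levenberg-Marquardt performs the final
# minimisation.

#' Fitting configuration
#'
#' @param n_particles particles per forward-model evaluation in the final
#'   Levenberg-Marquardt stage (production fits: 50,000, matching the
#'   scrambled-guide analysis; reduce for quick runs).
#' @param pre_particles particles per evaluation in the Nelder-Mead
#'   pre-stage.
#' @param pre_evals maximum Nelder-Mead iterations per pre-stage round (0
#'   disables the pre-stage).
#' @param pre_rounds maximum pre-stage rounds; each round restarts
#'   Nelder-Mead from the previous optimum under a fresh frozen seed, and
#'   rounds stop early once the objective reaches `floor_factor` times the
#'   estimated noise floor (observation plus forward Monte-Carlo variance)
#'   or stops improving.
#' @param floor_factor multiple of the noise floor treated as converged.
#' @param multistart scale factors applied to the starting rates; the
#'   pre-stage runs once per start. Distinct starts can settle in distinct
#'   near-degenerate modes of the objective; all polished modes are kept
#'   and propagated into [bootstrap_ci()]. The default brackets the start
#'   from both sides of the sloppy valley, which removes the one-sided
#'   stall bias of a single start.
#' @param noise_reps localisation-noise draws per simulated path
#'   (conditional Monte Carlo; see [simulate_mixture_ensemble()]).
#' @param seed frozen seed reused for every objective evaluation (common
#'   random numbers make the stochastic objective deterministic in the
#'   parameters, so finite differences are meaningful).
#' @param max_iter Levenberg-Marquardt iteration cap of the final stage.
#' @param min_tracks minimum number of observed tracks required.
#' @param ftol,ptol LM convergence tolerances (see
#'   [minpack.lm::nls.lm.control()]).
#' @param epsfcn forward-difference scaling of the LM jacobian; the default
#'   gives ~1% relative steps, large enough to see through the residual
#'   Monte-Carlo granularity of the frozen-seed objective.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_particles = 50000, pre_particles = 10000,
                       pre_evals = 150, pre_rounds = 3, floor_factor = 1.25,
                       multistart = c(1, 0.25), noise_reps = 8, seed = 1234,
                       max_iter = 12, min_tracks = 1000, ftol = 1e-10,
                       ptol = 1e-8, epsfcn = 1e-4) {
  structure(list(n_particles = n_particles, pre_particles = pre_particles,
                 pre_evals = pre_evals, pre_rounds = pre_rounds,
                 floor_factor = floor_factor, multistart = multistart,
                 noise_reps = noise_reps, seed = seed, max_iter = max_iter,
                 min_tracks = min_tracks, ftol = ftol, ptol = ptol,
                 epsfcn = epsfcn),
            class = "fit_config")
}

#' Residuals between two density-normalised diffusion histograms
#'
#' Per-bin difference of counts divided by each histogram's own track count,
#' so histograms of different sizes are comparable and residuals sum to 0.
#'
#' @param observed,simulated `diff_histogram` objects on identical binning.
#' @return Numeric residual vector (one entry per bin).
#' @export
histogram_residuals <- function(observed, simulated) {
  if (length(observed$counts) != length(simulated$counts) ||
      max(abs(log(observed$bin_edges) - log(simulated$bin_edges))) > 1e-9) {
    stop("binning mismatch between observed and simulated histograms")
  }
  if (observed$n_tracks == 0 || simulated$n_tracks == 0) {
    stop("cannot normalise an empty histogram")
  }
  observed$counts / observed$n_tracks - simulated$counts / simulated$n_tracks
}

# Forward model: histogram of D* from a simulated ensemble at given rates.
# Initial states/positions are stationary, so the burn-in is statistically
# redundant and dropped here for speed.
forward_histogram <- function(rates, diffs, imaging, geometry, n_particles,
                              seed, noise_reps = 1, drop_burnin = TRUE) {
  if (drop_burnin) imaging$equilibration <- 0
  ts <- simulate_ensemble(n_particles, rates, diffs, imaging, geometry,
                          seed, keep_locs = FALSE, noise_reps = noise_reps)
  build_histogram(track_dstars(ts), imaging)
}

# Composite search parametrisation <-> rates. p = (log k_3D->1D, log t_NTI,
# log ratio, log k_PAM->1D) with ratio = k_1D->PAM / k_PAM->1D and
# k_1D->3D = (1 + ratio) / t_NTI; bijective and unconstrained.
par_to_rates <- function(p) {
  k31 <- exp(p[1]); tN <- exp(p[2]); ratio <- exp(p[3]); kp1 <- exp(p[4])
  kinetic_rates(k31, (1 + ratio) / tN, ratio * kp1, kp1)
}

rates_to_par <- function(k) {
  c(log(k[["k_3D_to_1D"]]), log(t_nti(k)),
    log(k[["k_1D_to_PAM"]] / k[["k_PAM_to_1D"]]), log(k[["k_PAM_to_1D"]]))
}

#' Fit kinetic rates to an observed diffusion histogram (MC-DDA)
#'
#' Minimises [histogram_residuals()] between the observed histogram and the
#' stochastic forward model ([simulate_ensemble()]) over the four kinetic
#' rates in a composite log parametrisation (positivity is enforced by
#' construction). A derivative-free Nelder-Mead pre-stage at
#' `config$pre_particles` navigates the long, weakly identified valley of
#' the objective from each multistart point; every pre-stage candidate is
#' then polished by Levenberg-Marquardt at `config$n_particles` under one
#' frozen seed. Distinct candidates may settle in distinct near-degenerate
#' modes (different kinetic regimes can produce nearly identical pooled
#' histograms); all polished modes are retained in the result. The best
#' mode is re-polished under an independent frozen seed: the midpoint of
#' the two estimates halves the frozen-realisation bias and their
#' difference measures the estimator's forward + optimisation noise, both
#' used by [bootstrap_ci()]. Diffusion coefficients are held fixed during
#' fitting.
#'
#' @param observed a `diff_histogram`.
#' @param init a [kinetic_rates()] starting point.
#' @param diffs a [state_diffusion()] (fixed).
#' @param imaging an [imaging_config()].
#' @param geometry a [cell_geometry()].
#' @param config a [fit_config()].
#' @return A `fit_result`: list with `rates` (a [kinetic_rates()]), `par`
#'   (composite parametrisation), `cand_par` (the two independently
#'   polished estimates of the best mode), `modes_par` (one polished
#'   estimate per multistart mode), `chi2`, `n_tracks`, `seed`,
#'   `converged`, `niter`, `ci_95` (NULL until [bootstrap_ci()] fills it).
#' @export
fit_rates <- function(observed, init, diffs, imaging, geometry,
                      config = fit_config()) {
  stopifnot(inherits(observed, "diff_histogram"))
  if (observed$n_tracks < config$min_tracks) {
    stop(sprintf("observed histogram has %d tracks; at least %d required",
                 observed$n_tracks, config$min_tracks))
  }
  resid_fn <- function(p, n, seed) {
    sim <- forward_histogram(par_to_rates(p), diffs, imaging, geometry, n,
                             seed, noise_reps = config$noise_reps)
    histogram_residuals(observed, sim)
  }
  par <- rates_to_par(init)
  if (config$pre_evals > 0 && config$pre_rounds > 0) {
    # noise floor: observation sampling variance plus empirical forward
    # Monte-Carlo variance at the starting point
    obs_d <- observed$counts / observed$n_tracks
    obs_var <- (1 - sum(obs_d^2)) / observed$n_tracks
    f1 <- resid_fn(par, config$pre_particles, config$seed + 7919)
    f2 <- resid_fn(par, config$pre_particles, config$seed + 8887)
    fwd_var <- sum((f1 - f2)^2) / 2
    floor_est <- obs_var + fwd_var
    run_prestage <- function(par0, start_id) {
      best <- Inf
      for (round in seq_len(config$pre_rounds)) {
        nm <- stats::optim(par0, function(p) {
          sum(resid_fn(p, config$pre_particles,
                       config$seed + 7919 * round + 101 * start_id)^2)
        }, method = "Nelder-Mead",
        control = list(maxit = config$pre_evals, reltol = 1e-9))
        par0 <- nm$par
        done <- nm$value <= config$floor_factor * floor_est ||
          nm$value > 0.97 * best   # < 3% gain per round: stalled
        best <- min(best, nm$value)
        if (done) break
      }
      par0
    }
    k0 <- as.numeric(init)[1:4]
    starts <- lapply(config$multistart, function(f) {
      rates_to_par(kinetic_rates(k0[1] * f, k0[2] * f, k0[3] * f, k0[4] * f))
    })
    cands <- lapply(seq_along(starts), function(i) {
      run_prestage(starts[[i]], i)
    })
  } else {
    cands <- list(par)
  }
  # Polish each pre-stage candidate under one frozen seed; keep all polished
  # modes. Re-polish the best under an independent frozen seed: the midpoint
  # halves the frozen-realisation bias, the difference measures estimator
  # noise.
  lm_polish <- function(p0, seed) {
    suppressWarnings(minpack.lm::nls.lm(
      par = p0,
      fn = function(p) resid_fn(p, config$n_particles, seed),
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iter, ftol = config$ftol, ptol = config$ptol,
        gtol = 0, epsfcn = config$epsfcn)))
  }
  fits <- lapply(cands, lm_polish, seed = config$seed)
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  modes_par <- do.call(rbind, lapply(fits, function(f) f$par))
  best <- which.min(dev)
  fit <- fits[[best]]
  fit_b <- lm_polish(fit$par, seed = config$seed + 555)
  cand_par <- rbind(fit$par, fit_b$par)
  fit$par <- colMeans(cand_par)
  modes_par[best, ] <- fit$par
  structure(list(
    rates = par_to_rates(fit$par),
    par = fit$par,
    cand_par = cand_par,
    modes_par = modes_par,
    ci_95 = NULL,
    chi2 = fit$deviance,
    n_tracks = observed$n_tracks,
    seed = config$seed,
    converged = fit$info %in% c(1:4, -1),  # -1: capped at max_iter after pre-stage
    niter = fit$niter,
    info = fit$info), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MC-DDA fit", if (!x$converged) "(NOT converged)", "\n")
  k <- as.numeric(x$rates)[1:4]
  nm <- names(x$rates)[1:4]
  for (i in 1:4) {
    ci <- if (!is.null(x$ci_95)) {
      sprintf("  [%.1f, %.1f]", x$ci_95[i, 1], x$ci_95[i, 2])
    } else ""
    cat(sprintf("  %-12s %8.2f s^-1%s\n", nm[i], k[i], ci))
  }
  cat(sprintf("  t_NTI = %.2f ms;  chi2 = %.3g;  n_tracks = %d\n",
              1000 * t_nti(x$rates), x$chi2, x$n_tracks))
  invisible(x)
}

#' Bootstrap confidence intervals for fitted rates
#'
#' Resamples the observed tracks with replacement `n_boot` times and refits
#' each replicate, warm-started at the point estimate. With
#' `method = "one-step"` (default) each replicate refit is a single damped
#' Gauss-Newton step, using one jacobian of the forward model per mode
#' shared across replicates - first-order equivalent to a full refit and
#' orders of magnitude cheaper. Three noise sources are represented
#' honestly: (i) each replicate is compared against a fresh forward-model
#' realisation at the point estimate, so forward Monte-Carlo noise enters
#' the replicate spread; (ii) when the multistart fit retained several
#' near-degenerate modes, each replicate takes its Gauss-Newton step at
#' every mode and keeps the mode with the smaller post-step residual, so
#' mode ambiguity widens the intervals; (iii) the difference between the
#' two independently polished estimates of the best mode is convolved into
#' the replicates along its direction (estimator optimisation noise).
#' `method = "full"` reruns [fit_rates()] per replicate (expensive;
#' includes all noise sources by construction). Returns 2.5/97.5 percentile
#' intervals per rate and for the composite t_NTI.
#'
#' @param tracks a `track_set` (observed tracks), or a numeric vector of
#'   per-track D* values.
#' @param fit a `fit_result` from [fit_rates()] on these tracks.
#' @param diffs,imaging,geometry as in [fit_rates()].
#' @param config a [fit_config()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed seed for the resampling RNG.
#' @param method `"one-step"` or `"full"`.
#' @return List with `ci_95` (4 x 2 matrix, rows named by rate), `t_nti_ci`
#'   (length 2), `replicates` (matrix of per-replicate rates), `n_failed`.
#' @export
bootstrap_ci <- function(tracks, fit, diffs, imaging, geometry,
                         config = fit_config(), n_boot = 20, seed = 1,
                         method = c("one-step", "full")) {
  method <- match.arg(method)
  stopifnot(n_boot >= 2, inherits(fit, "fit_result"))
  d_all <- if (is.numeric(tracks)) tracks else track_dstars(tracks)
  n <- length(d_all)
  reps <- matrix(NA_real_, n_boot, 4)
  reps_par <- matrix(NA_real_, n_boot, 4)
  ok <- logical(n_boot)
  if (method == "one-step") {
    # deduplicate retained modes (distance in the composite parametrisation)
    modes <- list(fit$par)
    if (!is.null(fit$modes_par)) {
      for (m in seq_len(nrow(fit$modes_par))) {
        pm <- fit$modes_par[m, ]
        if (all(vapply(modes, function(q) sqrt(sum((q - pm)^2)) > 0.05,
                       logical(1)))) {
          modes <- c(modes, list(pm))
        }
      }
    }
    # per mode: frozen-seed forward density and jacobian at the estimate
    hstep <- 0.05
    mode_info <- lapply(modes, function(pm) {
      sim_hat <- forward_histogram(par_to_rates(pm), diffs, imaging,
                                   geometry, config$n_particles,
                                   config$seed, noise_reps = config$noise_reps)
      sim_d <- sim_hat$counts / sim_hat$n_tracks
      J <- matrix(0, length(sim_d), 4)
      for (i in 1:4) {
        p2 <- pm; p2[i] <- p2[i] + hstep
        sim_i <- forward_histogram(par_to_rates(p2), diffs, imaging,
                                   geometry, config$n_particles,
                                   config$seed, noise_reps = config$noise_reps)
        J[, i] <- -(sim_i$counts / sim_i$n_tracks - sim_d) / hstep
      }
      JtJ <- crossprod(J)
      list(par = pm, J = J, JtJ = JtJ,
           damp = 1e-6 * diag(diag(JtJ), 4))
    })
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        h_b <- build_histogram(d_all[sample.int(n, n, replace = TRUE)],
                               imaging)
        obs_b <- h_b$counts / h_b$n_tracks
        best_par <- NULL
        best_score <- Inf
        for (mi in mode_info) {
          # fresh forward realisation: replicate spread includes the
          # forward Monte-Carlo noise that also perturbs the estimate
          sim_b <- forward_histogram(par_to_rates(mi$par), diffs, imaging,
                                     geometry, config$n_particles,
                                     config$seed + 131 * b,
                                     noise_reps = config$noise_reps)
          r_b <- obs_b - sim_b$counts / sim_b$n_tracks
          delta <- tryCatch(solve(mi$JtJ + mi$damp, -crossprod(mi$J, r_b)),
                            error = function(e) NULL)
          if (is.null(delta)) next
          score <- sum((r_b + mi$J %*% delta)^2)
          if (score < best_score) {
            best_score <- score
            best_par <- mi$par + as.numeric(delta)
          }
        }
        if (!is.null(best_par)) {
          reps_par[b, ] <- best_par
          ok[b] <- TRUE
        }
      }
      # estimator-noise component: the m independently polished fits of the
      # best mode scatter around their mean with the estimator's forward +
      # optimisation noise; resampling their deviation vectors (scaled by
      # 1/sqrt(m-1) for the variance of the mean) convolves that noise into
      # the replicates along its measured directions
      if (!is.null(fit$cand_par) && nrow(fit$cand_par) >= 2) {
        m <- nrow(fit$cand_par)
        center <- colMeans(fit$cand_par)
        z <- rnorm(n_boot)
        pick <- sample.int(m, n_boot, replace = TRUE)
        for (b in which(ok)) {
          dirv <- (fit$cand_par[pick[b], ] - center) / sqrt(m - 1)
          reps_par[b, ] <- reps_par[b, ] + z[b] * dirv
        }
      }
      for (b in which(ok)) {
        reps[b, ] <- as.numeric(par_to_rates(reps_par[b, ]))[1:4]
      }
    })
  } else {
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        h_b <- build_histogram(d_all[sample.int(n, n, replace = TRUE)],
                               imaging)
        cfg_b <- config
        cfg_b$seed <- config$seed + b
        fit_b <- tryCatch(
          fit_rates(h_b, fit$rates, diffs, imaging, geometry, cfg_b),
          error = function(e) NULL)
        if (!is.null(fit_b) && fit_b$converged) {
          reps_par[b, ] <- fit_b$par
          reps[b, ] <- as.numeric(fit_b$rates)[1:4]
          ok[b] <- TRUE
        }
      }
    })
  }
  if (sum(ok) < 2) stop("fewer than 2 usable bootstrap replicates")
  good <- reps[ok, , drop = FALSE]
  ci <- t(apply(good, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  rownames(ci) <- names(fit$rates)[1:4]
  colnames(ci) <- c("lo", "hi")
  # t_NTI is exactly exp(par[2]) in the search parametrisation
  tn <- exp(reps_par[ok, 2])
  list(ci_95 = ci,
       t_nti_ci = quantile(tn, c(0.025, 0.975), names = FALSE),
       replicates = good,
       n_failed = sum(!ok))
}

#' Fit the target-bound fraction of a two-species mixture
#'
#' The searching species moves in the three-state model with rates fixed
#' from the scrambled-guide fit; the bound species diffuses with `D_Target`.
#' Both species are simulated once at `n_particles` each with frozen seeds;
#' the mixture histogram at fraction f is the density mixture
#' (1-f) searching + f bound, and f is found by least-squares grid search on
#' {0, 0.01, ..., 1} (ties break toward the smaller fraction). The grid
#' search replaces visual inspection of the overlays with a reproducible
#' criterion.
#'
#' @param observed a `diff_histogram`.
#' @param searching_rates a [kinetic_rates()] from the scrambled-guide fit.
#' @param diffs,imaging,geometry as in [fit_rates()].
#' @param n_particles particles per species (production: 250,000).
#' @param seed frozen seed for the species simulations.
#' @param grid candidate fractions.
#' @param noise_reps localisation-noise draws per path.
#' @return A `bound_fraction_result`: list with `fraction`, `sse`, `grid`,
#'   `sse_grid`.
#' @export
fit_bound_fraction <- function(observed, searching_rates, diffs, imaging,
                               geometry, n_particles = 250000, seed = 1234,
                               grid = seq(0, 1, by = 0.01), noise_reps = 4) {
  h_search <- forward_histogram(searching_rates, diffs, imaging, geometry,
                                n_particles, seed, noise_reps = noise_reps)
  imaging_nb <- imaging
  imaging_nb$equilibration <- 0
  ts_bound <- simulate_mixture_ensemble(n_particles, 1, searching_rates,
                                        diffs, imaging_nb, geometry, seed + 1,
                                        keep_locs = FALSE,
                                        noise_reps = noise_reps)
  h_bound <- build_histogram(track_dstars(ts_bound), imaging)
  obs_d <- observed$counts / observed$n_tracks
  s_d <- h_search$counts / h_search$n_tracks
  b_d <- h_bound$counts / h_bound$n_tracks
  sse <- vapply(grid, function(f) sum((obs_d - ((1 - f) * s_d + f * b_d))^2),
                numeric(1))
  best <- which.min(sse)   # first minimum: ties break toward smaller fraction
  structure(list(fraction = grid[best], sse = sse[best], grid = grid,
                 sse_grid = sse), class = "bound_fraction_result")
}

#' Target-bound fractions per track-count group
#'
#' Applies [fit_bound_fraction()] to each cell group of
#' [group_cells_by_track_count()].
#'
#' @param groups named list of `track_set` objects.
#' @param searching_rates,diffs,imaging,geometry,n_particles,seed as in
#'   [fit_bound_fraction()].
#' @return Data frame with columns `group`, `n_tracks`, `fraction`, `sse`.
#' @export
bound_fraction_by_group <- function(groups, searching_rates, diffs, imaging,
                                    geometry, n_particles = 250000,
                                    seed = 1234) {
  rows <- lapply(names(groups), function(g) {
    h <- build_histogram(track_dstars(groups[[g]]), imaging)
    r <- fit_bound_fraction(h, searching_rates, diffs, imaging, geometry,
                            n_particles, seed)
    data.frame(group = g, n_tracks = h$n_tracks, fraction = r$fraction,
               sse = r$sse)
  })
  do.call(rbind, rows)
}
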