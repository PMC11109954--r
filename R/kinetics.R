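# Closed-form kinetics of the linear three-state search cycle
# 3D <-> 1D <-> PAM, with uncertainty propagation and a stochastic oracle.

#' Splitting probabilities out of the 1D sliding state
#'
#' From the 1D state a nuclease either proceeds to PAM investigation or
#' releases into 3D diffusion; the two competing exponential transitions give
#' splitting probabilities proportional to their rates.
#'
#' @param rates a [kinetic_rates()].
#' @return Named vector `c(p_1D_to_PAM, p_1D_to_3D)`, summing to 1.
#' @examples
#' splitting_probabilities(kinetic_rates(20, 50, 100, 200))
#' @export
splitting_probabilities <- function(rates) {
  k13 <- rates[["k_1D_to_3D"]]; k1p <- rates[["k_1D_to_PAM"]]
  tot <- k13 + k1p
  if (tot <= 0) stop("both exit rates from the 1D state are zero")
  c(p_1D_to_PAM = k1p / tot, p_1D_to_3D = k13 / tot)
}

#' Mean dwell times of the 1D and PAM states
#'
#' @param rates a [kinetic_rates()].
#' @return Named vector `c(tau_1D, tau_PAM)` in seconds; `Inf` flags a state
#'   with zero exit rate.
#' @export
dwell_times <- function(rates) {
  k13 <- rates[["k_1D_to_3D"]]; k1p <- rates[["k_1D_to_PAM"]]
  kp1 <- rates[["k_PAM_to_1D"]]
  tau_1D <- if (k13 + k1p > 0) 1 / (k13 + k1p) else Inf
  tau_PAM <- if (kp1 > 0) 1 / kp1 else Inf
  c(tau_1D = tau_1D, tau_PAM = tau_PAM)
}

#' Non-target interaction time (closed form)
#'
#' Mean duration of a DNA-bound excursion: from entering 1D sliding to
#' returning to 3D diffusion, including any number of PAM-investigation
#' visits. Summing the geometric trajectory series gives
#' \deqn{t_{NTI} = \frac{k_{1D \to PAM} + k_{PAM \to 1D}}
#'                      {k_{PAM \to 1D} \cdot k_{1D \to 3D}}.}
#'
#' @param rates a [kinetic_rates()].
#' @return Time in seconds.
#' @examples
#' t_nti(kinetic_rates(20, 50, 100, 200))  # 0.030 s
#' @export
t_nti <- function(rates) {
  k13 <- rates[["k_1D_to_3D"]]; k1p <- rates[["k_1D_to_PAM"]]
  kp1 <- rates[["k_PAM_to_1D"]]
  if (k13 <= 0) stop("k_1D_to_3D must be positive")
  if (kp1 <= 0) {
    if (k1p > 0) stop("k_PAM_to_1D must be positive when k_1D_to_PAM > 0")
    return(1 / k13)
  }
  (k1p + kp1) / (kp1 * k13)
}

#' Non-target interaction time by trajectory-series summation
#'
#' Partial sum \eqn{\sum_{n=0}^{N} \tau_n P_n} over trajectories with exactly
#' `n` PAM visits, where \eqn{P_n = p_{1D\to PAM}^n \, p_{1D\to 3D}} and
#' \eqn{\tau_n = \tau_{1D} + n(\tau_{1D} + \tau_{PAM})}. Converges to the
#' closed form of [t_nti()]; exposed for verification.
#'
#' @param rates a [kinetic_rates()].
#' @param n_max largest number of PAM visits included.
#' @return Partial-sum time in seconds.
#' @export
t_nti_series <- function(rates, n_max = 50) {
  sp <- splitting_probabilities(rates)
  tau <- dwell_times(rates)
  n <- 0:n_max
  p_n <- sp[["p_1D_to_PAM"]]^n * sp[["p_1D_to_3D"]]
  tau_n <- tau[["tau_1D"]] + n * (tau[["tau_1D"]] + tau[["tau_PAM"]])
  sum(tau_n * p_n)
}

#' Uncertainty of the non-target interaction time
#'
#' Propagates uncorrelated rate uncertainties through the closed form with
#' hand-derived partial derivatives:
#' \eqn{\partial t/\partial k_{1D\to 3D} = -t_{NTI}/k_{1D\to 3D}},
#' \eqn{\partial t/\partial k_{1D\to PAM} = 1/(k_{PAM\to 1D} k_{1D\to 3D})},
#' \eqn{\partial t/\partial k_{PAM\to 1D} = -k_{1D\to PAM}/(k_{PAM\to 1D}^2 k_{1D\to 3D})}.
#'
#' @param rates a [kinetic_rates()].
#' @param rate_sigmas named numeric: standard errors of `k_1D_to_3D`,
#'   `k_1D_to_PAM`, `k_PAM_to_1D` (s^-1); missing names are treated as 0.
#' @return Standard error of t_NTI in seconds.
#' @export
t_nti_uncertainty <- function(rates, rate_sigmas) {
  k13 <- rates[["k_1D_to_3D"]]; k1p <- rates[["k_1D_to_PAM"]]
  kp1 <- rates[["k_PAM_to_1D"]]
  stopifnot(k13 > 0, kp1 > 0)
  s <- function(nm) if (nm %in% names(rate_sigmas)) rate_sigmas[[nm]] else 0
  stopifnot(s("k_1D_to_3D") >= 0, s("k_1D_to_PAM") >= 0, s("k_PAM_to_1D") >= 0)
  t <- t_nti(rates)
  d13 <- -t / k13
  d1p <- 1 / (kp1 * k13)
  dp1 <- -k1p / (kp1^2 * k13)
  sqrt((d13 * s("k_1D_to_3D"))^2 + (d1p * s("k_1D_to_PAM"))^2 +
       (dp1 * s("k_PAM_to_1D"))^2)
}

#' Stationary state fractions of the search cycle
#'
#' Detailed balance on the linear chain 3D <-> 1D <-> PAM:
#' \eqn{f_{3D} k_{3D\to 1D} = f_{1D} k_{1D\to 3D}} and
#' \eqn{f_{1D} k_{1D\to PAM} = f_{PAM} k_{PAM\to 1D}}, normalised to 1.
#' These fractions initialise simulated particles and summarise the average
#' partitioning of a nuclease population over the three searching states.
#'
#' @param rates a [kinetic_rates()].
#' @return Named vector `c(f_3D, f_1D, f_PAM)`.
#' @examples
#' steady_state_fractions(kinetic_rates(20, 40, 100, 200))  # 4/7, 2/7, 1/7
#' @export
steady_state_fractions <- function(rates) {
  k31 <- rates[["k_3D_to_1D"]]; k13 <- rates[["k_1D_to_3D"]]
  k1p <- rates[["k_1D_to_PAM"]]; kp1 <- rates[["k_PAM_to_1D"]]
  if (k31 <= 0) {
    if (any(c(k13, k1p, kp1) < 0)) stop("negative rate")
    return(c(f_3D = 1, f_1D = 0, f_PAM = 0))
  }
  if (k13 <= 0) stop("chain not irreducible: k_1D_to_3D is zero")
  f3 <- 1
  f1 <- f3 * k31 / k13
  fp <- if (k1p <= 0) 0 else {
    if (kp1 <= 0) stop("chain not irreducible: absorbing PAM state")
    f1 * k1p / kp1
  }
  tot <- f3 + f1 + fp
  c(f_3D = f3 / tot, f_1D = f1 / tot, f_PAM = fp / tot)
}

#' Exact jump-chain Monte-Carlo oracle for the non-target interaction time
#'
#' Simulates complete 1D-entry to 3D-return excursions of the embedded jump
#' chain event-exactly (exponential sojourns, geometric numbers of PAM
#' visits) and reports the empirical mean excursion duration with its
#' standard error, plus time-weighted state fractions over full cycles
#' including the 3D sojourns. Used as an independent check of the closed
#' forms; not a replacement for them.
#'
#' @param rates a [kinetic_rates()].
#' @param n_cycles number of excursions simulated.
#' @param seed integer seed.
#' @return List with `t_nti_hat`, `se`, `fractions` (time-weighted, named as
#'   in [steady_state_fractions()]) and `n_cycles`.
#' @export
ctmc_oracle <- function(rates, n_cycles = 1e5, seed = 1) {
  stopifnot(n_cycles >= 1)
  sp <- splitting_probabilities(rates)
  k31 <- rates[["k_3D_to_1D"]]; k13 <- rates[["k_1D_to_3D"]]
  k1p <- rates[["k_1D_to_PAM"]]; kp1 <- rates[["k_PAM_to_1D"]]
  with_seed(seed, {
    m <- rgeom(n_cycles, sp[["p_1D_to_3D"]])   # PAM visits per excursion
    t_1d <- rgamma_safe(n_cycles, m + 1, k13 + k1p)
    t_pam <- rgamma_safe(n_cycles, m, kp1)
    dur <- t_1d + t_pam
    t_3d <- if (k31 > 0) rgamma_safe(n_cycles, 1, k31) else rep(0, n_cycles)
    tot <- sum(t_3d) + sum(dur)
    list(t_nti_hat = mean(dur),
         se = sd(dur) / sqrt(n_cycles),
         fractions = c(f_3D = sum(t_3d) / tot, f_1D = sum(t_1d) / tot,
                       f_PAM = sum(t_pam) / tot),
         n_cycles = n_cycles)
  })
}

#' Kinetic report for a set of nucleases
#'
#' Closed-form non-target interaction times (ms) with propagated
#' uncertainties and stationary state fractions (%), one row per rate set.
#'
#' @param rate_sets named list of [kinetic_rates()].
#' @param sigma_sets optional named list of rate standard errors (named
#'   numeric vectors as in [t_nti_uncertainty()]).
#' @return A data frame with columns `label`, `t_nti_ms`, `sigma_t_nti_ms`,
#'   `f_3D_pct`, `f_1D_pct`, `f_PAM_pct`.
#' @export
kinetic_report <- function(rate_sets, sigma_sets = NULL) {
  stopifnot(is.list(rate_sets), length(rate_sets) >= 1)
  rows <- lapply(names(rate_sets), function(nm) {
    r <- rate_sets[[nm]]
    f <- steady_state_fractions(r)
    sig <- if (!is.null(sigma_sets) && nm %in% names(sigma_sets)) {
      t_nti_uncertainty(r, sigma_sets[[nm]])
    } else NA_real_
    data.frame(label = nm, t_nti_ms = 1000 * t_nti(r),
               sigma_t_nti_ms = 1000 * sig,
               f_3D_pct = 100 * f[["f_3D"]], f_1D_pct = 100 * f[["f_1D"]],
               f_PAM_pct = 100 * f[["f_PAM"]])
  })
  do.call(rbind, rows)
}

# rgamma with shape possibly 0 (point mass at 0) and vectorised shape.
rgamma_safe <- function(n, shape, rate) {
  out <- numeric(n)
  shape <- rep_len(shape, n)
  pos <- shape > 0
  if (any(pos)) out[pos] <- rgamma(sum(pos), shape = shape[pos], rate = rate)
  out
}

# Evaluate expr under a temporary R RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
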