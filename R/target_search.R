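# Target-finding predictions: PAM densities from genome composition, the
# per-episode target-encounter probability, an event-exact search sampler,
# t_50% extraction, and GC-content sweeps.

#' Per-position per-strand PAM density from GC content
#'
#' Under an i.i.d. base model with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2, the probability that a random position starts a
#' motif is the product over motif positions of the summed base
#' probabilities of each IUPAC class; densities of a non-overlapping motif
#' set add.
#'
#' @param pam a [pam_spec()].
#' @param gc GC fraction in (0, 1).
#' @return Probability per position per strand.
#' @examples
#' pam_density_from_gc(pam_spec("NGG"), 0.5)   # 0.0625
#' pam_density_from_gc(pam_spec("TTTV"), 0.5)  # 0.01171875
#' @export
pam_density_from_gc <- function(pam, gc) {
  stopifnot(gc > 0, gc < 1)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  class_p <- function(ch) {
    bases <- strsplit(iupac_bases(ch), "")[[1]]
    sum(base_p[bases])
  }
  motif_p <- vapply(pam$motifs, function(m) {
    prod(vapply(strsplit(m, "")[[1]], class_p, numeric(1)))
  }, numeric(1))
  sum(motif_p)
}

iupac_bases <- function(ch) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  out <- map[ch]
  if (any(is.na(out))) stop("invalid IUPAC character: ", ch[is.na(out)][1])
  out
}

#' Expected PAM count of a genome/plasmid background
#'
#' Expected number of motif occurrences over all genome and plasmid copies
#' and both strands, \eqn{n_{PAM} = \rho \cdot 2 \cdot (L_g C_g + L_p C_p)},
#' with the per-position density from [pam_density_from_gc()]. For the
#' per-episode encounter probability this count is combined with the number
#' of unbound target sites via [p_target()].
#'
#' @param genome a [genome_model()].
#' @param pam a [pam_spec()].
#' @return A `pam_census`: list with `n_pams`, `density_per_bp` and
#'   `p_target` (for zero bound proteins and `n_1D_pam = 1`).
#' @export
expected_pam_count <- function(genome, pam) {
  density <- pam_density_from_gc(pam, genome$gc_content)
  bp <- genome$genome_length * genome$genome_copy +
    genome$plasmid_length * genome$plasmid_copy
  n_pams <- density * 2 * bp
  structure(list(n_pams = n_pams, density_per_bp = density,
                 p_target = p_target(genome$n_targets, 0, n_pams, 1)),
            class = "pam_census")
}

#' @export
print.pam_census <- function(x, ...) {
  cat(sprintf("pam_census: %.4g expected motifs (density %.4g /bp/strand), p_target = %.3g\n",
              x$n_pams, x$density_per_bp, x$p_target))
  invisible(x)
}

#' Exact PAM count of a DNA sequence
#'
#' Sliding-window IUPAC match count on the sequence and its reverse
#' complement, overlaps allowed. Serves as the sequence-scan oracle for
#' [expected_pam_count()] and for exact counting from a FASTA genome.
#'
#' @param sequence a DNA string over A/C/G/T, a `Biostrings::DNAString`, or
#'   the path of a FASTA file (all records are summed).
#' @param pam a [pam_spec()].
#' @return Integer count over both strands.
#' @examples
#' scan_pams("TTTATTTC", pam_spec("TTTV"))  # 2
#' @export
scan_pams <- function(sequence, pam) {
  if (is.character(sequence) && length(sequence) == 1 &&
      file.exists(sequence) && grepl("\\.(fa|fasta|fna)$", sequence,
                                     ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(sequence)
  } else if (methods::is(sequence, "DNAString")) {
    seqs <- Biostrings::DNAStringSet(sequence)
  } else {
    seqs <- Biostrings::DNAStringSet(toupper(sequence))
  }
  for (s in as.character(seqs)) {
    if (grepl("[^ACGT]", s)) stop("ambiguous bases in input sequence")
  }
  total <- 0L
  for (m in pam$motifs) {
    pat <- Biostrings::DNAString(m)
    fwd <- sum(Biostrings::vcountPattern(pat, seqs, fixed = FALSE))
    rev <- sum(Biostrings::vcountPattern(
      pat, Biostrings::reverseComplement(seqs), fixed = FALSE))
    total <- total + fwd + rev
  }
  total
}

#' Per-episode target-encounter probability
#'
#' Probability that a 1D sliding episode encounters a PAM followed by the
#' correct protospacer:
#' \deqn{P_{target} = \frac{\#\,targets - \#\,bound}{\#\,PAM\ motifs} \cdot n_{1D_{PAM}},}
#' clamped to \eqn{[0, 1]}; `n_1D_pam` is the average number of PAM motifs
#' encountered while sliding on a random stretch of DNA.
#'
#' @param n_targets number of target sites.
#' @param n_bound number of already-bound proteins.
#' @param n_pams total PAM motif count (see [expected_pam_count()]).
#' @param n_1D_pam expected PAM encounters per 1D episode.
#' @return Probability in \eqn{[0, 1]}.
#' @export
p_target <- function(n_targets, n_bound, n_pams, n_1D_pam) {
  stopifnot(n_bound <= n_targets, n_pams > 0)
  min(1, max(0, (n_targets - n_bound) / n_pams * n_1D_pam))
}

# Event-exact first-binding time sampler for one unit searching one target.
#
# Per-episode mode: a Bernoulli(p) trial at each 3D->1D entry; on success the
# unit binds at the end of that 1D sojourn. With N ~ Geom(p) failed episodes
# and V ~ NegBin(N, p_1D->3D) PAM visits across them, the binding time is the
# sum of independent gamma variates:
#   Gamma(N+1, k_3D->1D) + Gamma(N+V+1, k_1D->3D + k_1D->PAM) + Gamma(V, k_PAM->1D).
# Per-PAM-visit mode: a trial at each PAM entry; with K ~ Geom(p) failed
# visits and W ~ NegBin(K+1, p_1D->PAM) 1D sojourns ending in 3D, binding at
# the (K+1)-th PAM entry gives
#   Gamma(W+1, k_3D->1D) + Gamma(K+W+1, k_1D->3D + k_1D->PAM) + Gamma(K, k_PAM->1D).
sample_binding_times <- function(n, rates, p, trial_mode) {
  if (p <= 0) return(rep(Inf, n))
  k31 <- rates[["k_3D_to_1D"]]
  exit1 <- rates[["k_1D_to_3D"]] + rates[["k_1D_to_PAM"]]
  kp1 <- rates[["k_PAM_to_1D"]]
  sp <- splitting_probabilities(rates)
  if (trial_mode == "per-episode") {
    N <- rgeom(n, p)
    V <- ifelse(N > 0, rnbinom(n, size = pmax(N, 1), prob = sp[["p_1D_to_3D"]]), 0)
    rgamma_safe(n, N + 1, k31) + rgamma_safe(n, N + V + 1, exit1) +
      rgamma_safe(n, V, kp1)
  } else {
    if (sp[["p_1D_to_PAM"]] <= 0) return(rep(Inf, n))
    K <- rgeom(n, p)
    W <- rnbinom(n, size = K + 1, prob = sp[["p_1D_to_PAM"]])
    rgamma_safe(n, W + 1, k31) + rgamma_safe(n, K + W + 1, exit1) +
      rgamma_safe(n, K, kp1)
  }
}

#' Simulate target search of a cell population
#'
#' Event-exact simulation of the jump chain 3D -> 1D -> {PAM, 3D, Target}:
#' exponential sojourns with the configured rates, a Bernoulli(P_target)
#' trial per 1D episode (or per PAM visit, see [search_params()]), and
#' irreversible binding (k_Target->3D = 0). Spatial coordinates never enter
#' the encounter probability, so the chain is sampled without positions;
#' see [search_spatial()] for the position-resolved cross-check. Each of
#' `n_repeats` ensembles simulates `n_cells` cells with `n_units` units; the
#' output is the mean and standard deviation over ensembles of the fraction
#' of cells whose targets are all bound by each time.
#'
#' With a single target the sampler is exact. With several targets,
#' unbound units are restarted memorylessly whenever a binding changes
#' P_target; the error is of the order of one search cycle, negligible
#' against binding times.
#'
#' @param rates a [kinetic_rates()].
#' @param genome a [genome_model()].
#' @param pam a [pam_spec()].
#' @param params a [search_params()].
#' @param seed integer seed.
#' @param times evaluation time grid (s); default 400 log-spaced points up
#'   to `params$t_max`.
#' @return A `search_curve`: list with `times`, `fraction_found`, `sd`,
#'   `census` (the [expected_pam_count()] used) and `params`.
#' @export
simulate_search <- function(rates, genome, pam, params = search_params(),
                            seed = 1, times = NULL) {
  census <- expected_pam_count(genome, pam)
  if (is.null(times)) {
    t_lo <- min(1, params$t_max)
    times <- unique(c(0, exp(seq(log(max(t_lo, 1e-6)), log(max(params$t_max, 1e-6)),
                                 length.out = 400))))
  }
  frac <- matrix(NA_real_, params$n_repeats, length(times))
  with_seed(seed, {
    for (r in seq_len(params$n_repeats)) {
      t_cell <- cell_binding_times(rates, genome, census$n_pams, params)
      frac[r, ] <- vapply(times, function(tt) mean(t_cell <= tt), numeric(1))
    }
  })
  structure(list(times = times,
                 fraction_found = colMeans(frac),
                 sd = apply(frac, 2, sd),
                 census = census, params = params),
            class = "search_curve")
}

# Binding time (all targets bound) for each of n_cells cells.
cell_binding_times <- function(rates, genome, n_pams, params) {
  n_cells <- params$n_cells; n_units <- params$n_units
  n_targets <- genome$n_targets
  if (n_targets == 0) return(rep(0, n_cells))
  p0 <- p_target(n_targets, 0, n_pams, params$n_1D_pam)
  if (n_targets == 1) {
    tb <- matrix(sample_binding_times(n_cells * n_units, rates, p0,
                                      params$trial_mode),
                 n_cells, n_units)
    t_cell <- do.call(pmin, as.data.frame(tb))
    return(ifelse(t_cell <= params$t_max, t_cell, Inf))
  }
  # several targets: resample unbound units after each binding event
  t_cell <- numeric(n_cells)
  for (cell in seq_len(n_cells)) {
    now <- 0; bound <- 0; free <- n_units
    repeat {
      if (free == 0 || bound == n_targets) break
      p <- p_target(n_targets, bound, n_pams, params$n_1D_pam)
      cand <- min(sample_binding_times(free, rates, p, params$trial_mode))
      now <- now + cand
      if (now > params$t_max) { now <- Inf; break }
      bound <- bound + 1; free <- free - 1
    }
    t_cell[cell] <- if (bound == n_targets) now else Inf
  }
  t_cell
}

#' @export
print.search_curve <- function(x, ...) {
  t50 <- t50_from_curve(x)
  cat(sprintf("search_curve: %d cells x %d repeats, %d units; final fraction %.3f; t50 = %s\n",
              x$params$n_cells, x$params$n_repeats, x$params$n_units,
              x$fraction_found[length(x$fraction_found)],
              if (is.na(t50)) "not reached" else sprintf("%.3g s", t50)))
  invisible(x)
}

#' Time to 50% target-finding probability
#'
#' Linear interpolation of the mean curve between the two time points
#' bracketing 0.5.
#'
#' @param curve a `search_curve` (or list with `times` and
#'   `fraction_found`).
#' @return Time in seconds, or `NA` (with a warning) if the curve never
#'   reaches 0.5.
#' @export
t50_from_curve <- function(curve) {
  f <- curve$fraction_found; tt <- curve$times
  if (max(f) < 0.5) {
    warning("curve never reaches 0.5; t50 undefined")
    return(NA_real_)
  }
  i <- which(f >= 0.5)[1]
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]; t1 <- tt[i]; f0 <- f[i - 1]; f1 <- f[i]
  if (f1 == f0) return(t1)
  t0 + (0.5 - f0) / (f1 - f0) * (t1 - t0)
}

#' GC-content sweep of target-finding times
#'
#' For each GC value the PAM census is recomputed and a single-unit search
#' is simulated; reports t_50% and the expected PAM count. Default sweep:
#' 30% to 70% in steps of 10%.
#'
#' @param rates a [kinetic_rates()].
#' @param genome a [genome_model()] (its `gc_content` is overridden).
#' @param pam a [pam_spec()].
#' @param params a [search_params()]; `n_units` is forced to 1.
#' @param gc_values GC fractions to sweep.
#' @param seed integer seed.
#' @return Data frame with columns `gc`, `t50_s`, `n_pams`.
#' @export
gc_sweep <- function(rates, genome, pam, params = search_params(),
                     gc_values = seq(0.30, 0.70, by = 0.10), seed = 1) {
  params$n_units <- 1
  rows <- lapply(seq_along(gc_values), function(i) {
    g <- genome
    g$gc_content <- gc_values[i]
    curve <- simulate_search(rates, g, pam, params, seed = seed + i)
    data.frame(gc = gc_values[i],
               t50_s = suppressWarnings(t50_from_curve(curve)),
               n_pams = curve$census$n_pams)
  })
  do.call(rbind, rows)
}

#' Analytic mean first-binding time (single unit, constant P_target)
#'
#' First-passage algebra of the chain: the number of failed episodes is
#' geometric with success probability `p_target_value`, each failed cycle
#' lasts \eqn{1/k_{3D\to 1D} + t_{NTI}} on average, and the successful
#' episode adds one 3D sojourn plus one 1D sojourn, giving
#' \deqn{E[T] = (1/k_{3D\to 1D} + t_{NTI})/P_{target} - t_{NTI} + \tau_{1D}.}
#'
#' @param rates a [kinetic_rates()].
#' @param p_target_value constant per-episode success probability.
#' @return Expected first-binding time (s).
#' @export
analytic_search_oracle <- function(rates, p_target_value) {
  stopifnot(p_target_value > 0, p_target_value <= 1)
  tau1 <- dwell_times(rates)[["tau_1D"]]
  (1 / rates[["k_3D_to_1D"]] + t_nti(rates)) / p_target_value -
    t_nti(rates) + tau1
}

#' Position-resolved search simulation (cross-check)
#'
#' The grid-stepped, confined-diffusion analogue of [simulate_search()]:
#' one unit per cell, stepped at `t_step` with full spatial dynamics, a
#' Bernoulli(P_target) trial per 1D episode. Positions do not enter the
#' encounter probability; agreement with the event-driven sampler justifies
#' discarding them.
#'
#' @param rates a [kinetic_rates()].
#' @param p_target_value constant per-episode success probability.
#' @param t_max horizon (s).
#' @param n_cells number of cells.
#' @param diffs a [state_diffusion()].
#' @param geometry a [cell_geometry()].
#' @param t_step grid step (s).
#' @param seed integer seed.
#' @return Numeric vector of first-binding times (NA if not bound by
#'   `t_max`).
#' @export
search_spatial <- function(rates, p_target_value, t_max, n_cells = 100,
                           diffs = state_diffusion(),
                           geometry = cell_geometry(), t_step = 1e-4,
                           seed = 1) {
  .search_spatial_cpp(as.numeric(rates)[1:4], as.numeric(diffs),
                      p_target_value, t_max, as.integer(n_cells),
                      geometry$cylinder_length, geometry$radius, t_step,
                      as.numeric(seed))
}

#' Write a search curve as CSV
#' @param curve a `search_curve`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_search_curve <- function(curve, path) {
  write.csv(data.frame(time_s = curve$times, fraction = curve$fraction_found,
                       sd = curve$sd),
            path, row.names = FALSE)
  invisible(path)
}
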