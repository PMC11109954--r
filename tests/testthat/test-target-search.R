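test_that("PAM densities follow the i.i.d. base-composition model", {
  expect_equal(pam_density_from_gc(pam_spec("NNN"), 0.3), 1)
  expect_equal(pam_density_from_gc(pam_spec("NGG"), 0.5), 0.0625)
  expect_equal(pam_density_from_gc(pam_spec("TTTV"), 0.5), 0.01171875)
  # GC dependence: NGG density rises with GC, TTTV falls
  gcs <- seq(0.3, 0.7, 0.1)
  ngg <- sapply(gcs, function(g) pam_density_from_gc(pam_spec("NGG"), g))
  tttv <- sapply(gcs, function(g) pam_density_from_gc(pam_spec("TTTV"), g))
  expect_true(all(diff(ngg) > 0))
  expect_true(all(diff(tttv) < 0))
  # motif set densities add
  d4 <- pam_density_from_gc(pam_spec(c("TNTN", "TACV", "TTCV", "CTCV")), 0.5)
  expect_equal(d4, sum(sapply(c("TNTN", "TACV", "TTCV", "CTCV"), function(m) {
    pam_density_from_gc(pam_spec(m), 0.5)
  })))
})

test_that("expected PAM counts scale with genome content and match a sequence scan", {
  g <- genome_model(genome_length = 1e6, genome_copy = 1, plasmid_length = 0,
                    plasmid_copy = 0, gc_content = 0.5)
  cen <- expected_pam_count(g, pam_spec("NGG"))
  expect_equal(cen$n_pams, 0.0625 * 2 * 1e6)
  g2 <- g; g2$genome_copy <- 2
  expect_equal(expected_pam_count(g2, pam_spec("NGG"))$n_pams, 2 * cen$n_pams)
  # exact scan on a random sequence of matching composition
  set.seed(51)
  seq_str <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                   collapse = "")
  n_exact <- scan_pams(seq_str, pam_spec("NGG"))
  g3 <- genome_model(genome_length = 1e5, genome_copy = 1, plasmid_length = 0,
                     plasmid_copy = 0, gc_content = 0.5)
  n_exp <- expected_pam_count(g3, pam_spec("NGG"))$n_pams
  expect_lt(abs(n_exact - n_exp), 3 * sqrt(n_exp))
})

test_that("the sequence scanner counts IUPAC matches on both strands", {
  expect_equal(scan_pams("TTTATTTC", pam_spec("TTTV")), 2)
  s <- "ACGTACGTACG"
  expect_equal(scan_pams(s, pam_spec("NNN")), 2 * (nchar(s) - 2))
  expect_equal(scan_pams("", pam_spec("NGG")), 0)
  expect_error(scan_pams("ACGTN", pam_spec("NGG")), "ambiguous")
  # reverse-complement hits: CCA on the forward strand is TGG backwards
  expect_equal(scan_pams("CCAAAA", pam_spec("TGG")), 1)
  # FASTA input
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "TTTATTTC"), fa)
  expect_equal(scan_pams(fa, pam_spec("TTTV")), 2)
})

test_that("the target-encounter probability follows the displayed formula", {
  expect_equal(p_target(1, 0, 1e6, 1), 1e-6)
  expect_equal(p_target(3, 3, 1e6, 1), 0)
  expect_equal(p_target(1, 0, 1e6, 2), 2e-6)   # linear in n_1D_pam
  expect_equal(p_target(1, 0, 2, 10), 1)       # clamped at 1
  expect_error(p_target(1, 2, 1e6, 1))
})

test_that("t50 extraction interpolates the mean curve", {
  step <- list(times = 0:200, fraction_found = c(rep(0, 100), rep(1, 101)))
  expect_lte(abs(t50_from_curve(step) - 100), 1)
  tau <- 40
  tt <- seq(0, 400, by = 0.05)
  smooth <- list(times = tt, fraction_found = 1 - exp(-tt / tau))
  expect_lt(abs(t50_from_curve(smooth) - tau * log(2)) / (tau * log(2)), 0.001)
  # unit change of the grid rescales t50
  mins <- list(times = tt / 60, fraction_found = smooth$fraction_found)
  expect_equal(t50_from_curve(mins), t50_from_curve(smooth) / 60)
  flat <- list(times = 0:10, fraction_found = rep(0.2, 11))
  expect_warning(v <- t50_from_curve(flat), "never reaches")
  expect_true(is.na(v))
})

test_that("search curves are monotone in time and unit count", {
  r <- demo_rates()
  g <- genome_model()
  pam <- pam_spec("NGG")
  p1 <- search_params(n_cells = 300, n_repeats = 3, t_max = 2e5, n_units = 1)
  p10 <- search_params(n_cells = 300, n_repeats = 3, t_max = 2e5,
                       n_units = 10)
  c1 <- simulate_search(r, g, pam, p1, seed = 61)
  c10 <- simulate_search(r, g, pam, p10, seed = 62)
  expect_true(all(diff(c1$fraction_found) >= 0))
  expect_true(all(c10$fraction_found - c1$fraction_found >= -0.05))
  expect_true(all(c1$fraction_found >= 0 & c1$fraction_found <= 1))
  # t_max = 0: nothing can bind
  c0 <- simulate_search(r, g, pam, search_params(n_cells = 50, n_repeats = 2,
                                                 t_max = 0), seed = 63)
  expect_true(all(c0$fraction_found == 0))
})

test_that("with certain encounter the first 1D entry binds", {
  r <- demo_rates()
  g <- genome_model(genome_length = 1, genome_copy = 1, plasmid_length = 0,
                    plasmid_copy = 0)          # tiny genome
  g$n_targets <- 1
  pam <- pam_spec("NNN")
  # n_pams = 2 and n_1D_pam = 2 force p_target = 1
  prm <- search_params(n_cells = 4000, n_repeats = 2, t_max = 100,
                       n_1D_pam = 2)
  cen <- expected_pam_count(g, pam)
  expect_equal(p_target(1, 0, cen$n_pams, 2), 1)
  curve <- simulate_search(r, g, pam, prm, seed = 64,
                           times = seq(0, 0.5, by = 0.002))
  # mean first-binding time ~ 1/k_3D->1D + tau_1D
  expected <- analytic_search_oracle(r, 1)
  expect_equal(expected, 1 / 20 + dwell_times(r)[["tau_1D"]])
  t50 <- t50_from_curve(curve)
  expect_lt(abs(t50 - log(2) / 20 - dwell_times(r)[["tau_1D"]]) /
            (log(2) / 20), 0.25)
})

test_that("the analytic oracle matches the event-driven sampler", {
  r <- demo_rates()
  for (p in c(1e-2, 1e-3)) {
    oracle <- analytic_search_oracle(r, p)
    set.seed(65)
    t_sim <- mcdda:::sample_binding_times(4000, r, p, "per-episode")
    se <- sd(t_sim) / sqrt(length(t_sim))
    expect_lt(abs(mean(t_sim) - oracle), 3 * se)
  }
  # halving p_target doubles the time asymptotically
  expect_lt(abs(analytic_search_oracle(r, 5e-4) /
                analytic_search_oracle(r, 1e-3) - 2), 0.01)
  # per-pam-visit mode: mean time ~ (cycle mean per PAM trial)/p for small p
  set.seed(66)
  t_pam <- mcdda:::sample_binding_times(4000, r, 1e-2, "per-pam-visit")
  sp <- splitting_probabilities(r)
  tau <- dwell_times(r)
  cyc <- (tau[["tau_1D"]] + (1 / sp[["p_1D_to_PAM"]] - 1) *
            (1 / 20 + tau[["tau_1D"]])) + tau[["tau_PAM"]]
  approx_mean <- cyc / 1e-2
  expect_lt(abs(mean(t_pam) - approx_mean) / approx_mean, 0.15)
})

test_that("event-driven and position-resolved search agree on the mean first-binding time", {
  r <- demo_rates()
  p <- 1e-2
  t_spatial <- search_spatial(r, p, t_max = 150, n_cells = 100, seed = 67)
  t_spatial <- t_spatial[is.finite(t_spatial)]
  expect_gte(length(t_spatial), 99)
  set.seed(68)
  t_event <- mcdda:::sample_binding_times(100, r, p, "per-episode")
  se <- sqrt(sd(t_spatial)^2 / 100 + sd(t_event)^2 / 100)
  expect_lt(abs(mean(t_spatial) - mean(t_event)), 3 * se)
})

test_that("GC sweeps respond to the PAM motif as expected", {
  r <- demo_rates()
  g <- genome_model()
  prm <- search_params(n_cells = 200, n_repeats = 3, t_max = 1e7)
  sw_nnn <- gc_sweep(r, g, pam_spec("NNN"), prm, seed = 71)
  sw_ngg <- gc_sweep(r, g, pam_spec("NGG"), prm, seed = 72)
  sw_tttv <- gc_sweep(r, g, pam_spec("TTTV"), prm, seed = 73)
  # NNN: constant within sampling error
  expect_lt(max(sw_nnn$t50_s) / min(sw_nnn$t50_s), 1.35)
  # NGG: increasing with GC; TTTV: decreasing
  expect_true(all(diff(sw_ngg$t50_s) > 0))
  expect_true(all(diff(sw_tttv$t50_s) < 0))
  expect_true(all(diff(sw_ngg$n_pams) > 0))
  expect_true(all(diff(sw_tttv$n_pams) < 0))
})
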