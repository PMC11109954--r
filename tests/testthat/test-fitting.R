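test_that("histogram residuals are density-normalised differences", {
  im <- imaging_config()
  h1 <- build_histogram(c(0.1, 0.2, 0.5, 1), im)
  expect_equal(histogram_residuals(h1, h1), rep(0, 85))
  set.seed(41)
  h2 <- build_histogram(10^runif(200, log10(0.05), 0.9), im)
  r <- histogram_residuals(h1, h2)
  expect_equal(sum(r), 0)
  # disjoint single-bin histograms: +1 and -1 in the two occupied bins
  ha <- build_histogram(0.1, im)
  hb <- build_histogram(1, im)
  r2 <- histogram_residuals(ha, hb)
  expect_equal(sort(r2[r2 != 0]), c(-1, 1))
  im_small <- imaging_config(hist_bins = 40)
  h3 <- build_histogram(0.1, im_small)
  expect_error(histogram_residuals(h1, h3), "binning mismatch")
  expect_error(histogram_residuals(h1, build_histogram(numeric(0), im)),
               "empty")
})

test_that("the frozen-seed forward objective is deterministic in the parameters", {
  r <- demo_rates()
  h1 <- mcdda:::forward_histogram(r, state_diffusion(), imaging_config(),
                                  cell_geometry(), 5000, seed = 99,
                                  noise_reps = 4)
  h2 <- mcdda:::forward_histogram(r, state_diffusion(), imaging_config(),
                                  cell_geometry(), 5000, seed = 99,
                                  noise_reps = 4)
  expect_identical(h1$counts, h2$counts)
})

test_that("the composite search parametrisation is a bijection with the rates", {
  set.seed(42)
  for (i in 1:20) {
    k <- kinetic_rates(runif(1, 1, 50), runif(1, 10, 500),
                       runif(1, 10, 500), runif(1, 10, 500))
    back <- mcdda:::par_to_rates(mcdda:::rates_to_par(k))
    expect_equal(as.numeric(back)[1:4], as.numeric(k)[1:4], tolerance = 1e-12)
    # second component is exactly log t_NTI
    expect_equal(exp(mcdda:::rates_to_par(k)[2]), t_nti(k))
  }
})

test_that("a self-fit started at the truth stays at the truth", {
  r <- demo_rates()
  im <- fast_imaging()
  ge <- cell_geometry()
  obs <- simulate_ensemble(30000, r, state_diffusion(), im, ge, seed = 43,
                           keep_locs = FALSE)
  h <- build_histogram(track_dstars(obs), im)
  cfg <- quick_fit_config(seed = 44)
  cfg$pre_evals <- 0      # LM only, from the truth
  cfg$max_iter <- 6
  fit <- fit_rates(h, r, state_diffusion(), im, ge, cfg)
  expect_s3_class(fit, "fit_result")
  expect_lt(fit$chi2, 1e-4)    # at the Monte-Carlo noise floor
  expect_lt(abs(t_nti(fit$rates) - t_nti(r)) / t_nti(r), 0.10)
  k_hat <- as.numeric(fit$rates)[1:4]
  expect_lt(abs(k_hat[1] - 20) / 20, 0.15)   # k_3D->1D is well identified
})

test_that("fit_rates enforces the minimum track count", {
  h <- build_histogram(rep(0.2, 50), imaging_config())
  expect_error(fit_rates(h, demo_rates(), state_diffusion(), imaging_config(),
                         cell_geometry(), fit_config(min_tracks = 1000)),
               "at least 1000")
})

test_that("one-step bootstrap gives degenerate intervals for degenerate data and widens with less data", {
  r <- demo_rates()
  im <- fast_imaging()
  ge <- cell_geometry()
  obs <- simulate_ensemble(20000, r, state_diffusion(), im, ge, seed = 45,
                           keep_locs = FALSE)
  d <- track_dstars(obs)
  cfg <- quick_fit_config(seed = 46)
  cfg$pre_evals <- 0
  cfg$max_iter <- 3
  cfg$n_particles <- 8000
  h <- build_histogram(d, im)
  fit <- fit_rates(h, r, state_diffusion(), im, ge, cfg)
  boot_big <- bootstrap_ci(d, fit, state_diffusion(), im, ge, cfg,
                           n_boot = 12, seed = 1)
  boot_small <- bootstrap_ci(d[1:4000], fit, state_diffusion(), im, ge, cfg,
                             n_boot = 12, seed = 1)
  expect_true(all(boot_big$ci_95[, "lo"] <= as.numeric(fit$rates)[1:4] * 1.5))
  w_big <- diff(log(boot_big$t_nti_ci))
  w_small <- diff(log(boot_small$t_nti_ci))
  expect_gt(w_small, w_big)   # intervals widen as tracks decrease
  expect_equal(boot_big$n_failed, 0)
})

test_that("mixture-fraction grid search recovers the null and a true fraction", {
  r <- demo_rates()
  im <- fast_imaging()
  ge <- cell_geometry()
  # null case: searching-only data
  obs0 <- simulate_mixture_ensemble(30000, 0, r, state_diffusion(), im, ge,
                                    seed = 47, keep_locs = FALSE)
  h0 <- build_histogram(track_dstars(obs0), im)
  f0 <- fit_bound_fraction(h0, r, state_diffusion(), im, ge,
                           n_particles = 30000, seed = 48)
  expect_lte(f0$fraction, 0.02)
  # a 25% bound fraction at moderate scale
  obs <- simulate_mixture_ensemble(30000, 0.25, r, state_diffusion(), im, ge,
                                   seed = 49, keep_locs = FALSE)
  h <- build_histogram(track_dstars(obs), im)
  f <- fit_bound_fraction(h, r, state_diffusion(), im, ge,
                          n_particles = 30000, seed = 50)
  expect_lt(abs(f$fraction - 0.25), 0.04)
  # ties break toward the smaller fraction by construction of which.min
  expect_equal(f$grid[which.min(f$sse_grid)], f$fraction)
})
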