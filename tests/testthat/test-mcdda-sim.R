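test_that("state-change times follow the inverse-CDF exponential law", {
  expect_equal(draw_state_change_time(100, exp(-1)), 0.01)
  expect_equal(draw_state_change_time(50, 1), 0)
  expect_identical(draw_state_change_time(0, 0.5), Inf)
  expect_error(draw_state_change_time(50, 0), "\\(0, 1\\]")
  expect_error(draw_state_change_time(50, 1.5), "\\(0, 1\\]")
  set.seed(1)
  draws <- draw_state_change_time(50, runif(1e5))
  expect_lt(abs(mean(draws) - 0.02), 3 * sd(draws) / sqrt(1e5))
})

test_that("track-length sampler hits the calibrated truncated-exponential mean", {
  im <- imaging_config()
  set.seed(2)
  L <- sample_track_length(im, runif(1e5))
  expect_true(all(L >= 1 & L <= 8))
  expect_lt(abs(mean(L) - 3) / 3, 0.01)
  # degenerate boundary: mean at the lower support edge
  im1 <- imaging_config(mean_track_steps = 1)
  expect_true(all(sample_track_length(im1, runif(100)) == 1))
  # strictly decreasing pmf for the default mean
  tab <- tabulate(L, 8)
  expect_true(all(diff(tab) < 0))
  expect_error(sample_track_length(imaging_config(mean_track_steps = 12),
                                   0.5), "infeasible")
})

test_that("initial states are drawn from the stationary law", {
  r_eq <- kinetic_rates(5, 5, 5, 5)
  set.seed(3)
  s <- initial_state(r_eq, runif(3e4))
  frac <- table(factor(s, c("3D", "1D", "PAM"))) / 3e4
  expect_true(all(abs(frac - 1 / 3) < 3 * sqrt(1 / 3 * 2 / 3 / 3e4)))
  expect_true(all(initial_state(kinetic_rates(0, 40, 100, 200),
                                runif(100)) == "3D"))
  # cross-check against steady_state_fractions for an asymmetric chain
  r <- demo_rates()
  f <- steady_state_fractions(r)
  s2 <- initial_state(r, runif(3e4))
  frac2 <- table(factor(s2, c("3D", "1D", "PAM"))) / 3e4
  expect_true(all(abs(frac2 - f) < 3 * sqrt(f * (1 - f) / 3e4)))
})

test_that("position propagation has the Brownian scale and respects the wall", {
  ge <- cell_geometry()
  expect_equal(propagate_position(c(0.3, 0.1, 0), 0, ge, 1e-4, c(3, 3, 3)),
               c(0.3, 0.1, 0))
  expect_equal(propagate_position(c(0, 0, 0), 2, ge, 1e-4, c(1, 0, 0))[1],
               sqrt(2 * 2 * 1e-4))
  # large kicks in every direction stay inside the spherocylinder
  set.seed(4)
  for (i in 1:200) {
    p <- propagate_position(c(0.9, 0.3, -0.2), 2, ge, 0.05, rnorm(3))
    expect_true(mcdda:::inside_spherocylinder(p, ge))
  }
  # free-space variance accumulates over sub-steps (no boundary at this scale)
  tiny <- cell_geometry(cylinder_length = 200, radius = 100)
  set.seed(5)
  final <- replicate(4000, {
    pos <- c(0, 0, 0)
    for (s in 1:20) pos <- propagate_position(pos, 2, tiny, 5e-4, rnorm(3))
    pos[1]
  })
  expect_lt(abs(var(final) - 2 * 2 * 0.01), 4 * sqrt(2 / 4000) * (2 * 2 * 0.01))
})

test_that("simulated ensembles are deterministic, confined and stationary", {
  r <- demo_rates()
  im <- fast_imaging()
  ge <- cell_geometry()
  ts1 <- simulate_ensemble(3000, r, state_diffusion(), im, ge, seed = 11)
  ts2 <- simulate_ensemble(3000, r, state_diffusion(), im, ge, seed = 11)
  expect_identical(ts1$locs, ts2$locs)
  expect_identical(ts1$info, ts2$info)
  # every localisation within the cell cross-section plus 5 sigma of noise
  rad_max <- 0.5 + 5 * im$sigma_loc
  expect_true(all(abs(ts1$locs$y) <= rad_max))
  expect_true(all(abs(ts1$locs$x) <= 1 + 0.5 + 5 * im$sigma_loc))
  # track lengths follow the truncated exponential law
  expect_lt(abs(mean(ts1$info$length) - 3), 0.1)
  # empty ensemble
  e <- simulate_ensemble(0, r, state_diffusion(), im, ge, seed = 1)
  expect_equal(n_tracks(e), 0)
})

test_that("a particle frozen in the PAM state stays at its position up to noise", {
  # k_PAM->1D = 0 with k_1D->PAM > 0 is rejected as an absorbing state, so
  # freeze via an overwhelming PAM entry rate and a negligible exit rate
  r <- kinetic_rates(1e-9, 1e-9, 1e6, 1e-9)
  im <- fast_imaging()
  ts <- simulate_ensemble(300, r, state_diffusion(D_3D = 0), im,
                          cell_geometry(), seed = 6)
  spread <- tapply(seq_len(nrow(ts$locs)), ts$locs$track, function(i) {
    max(dist(cbind(ts$locs$x[i], ts$locs$y[i])))
  })
  expect_true(all(spread < 5 * im$sigma_loc * 2))
})

test_that("frame displacements of an unconfined 3D particle are Gaussian", {
  r <- kinetic_rates(0, 1, 0, 1)   # never leaves 3D
  im <- fast_imaging()
  huge <- cell_geometry(cylinder_length = 2000, radius = 1000)
  ts <- simulate_ensemble(4000, r, state_diffusion(), im, huge, seed = 12)
  dx <- unlist(tapply(ts$locs$x, ts$locs$track, diff))
  sd_exp <- sqrt(2 * 2 * im$frame_interval + 2 * im$sigma_loc^2)
  ks <- suppressWarnings(stats::ks.test(dx / sd_exp, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single simulated track feeds the D* estimator directly", {
  tr <- simulate_particle_track(demo_rates(), state_diffusion(),
                                fast_imaging(), cell_geometry(), seed = 19)
  expect_true(all(c("x", "y", "frame") %in% names(tr)))
  expect_gte(nrow(tr), 2)
  expect_lte(nrow(tr), 9)
  d <- estimate_dstar(tr, fast_imaging()$frame_interval)
  expect_gte(d, 0)
  expect_identical(tr, simulate_particle_track(demo_rates(), state_diffusion(),
                                               fast_imaging(), cell_geometry(),
                                               seed = 19))
})

test_that("long-run occupancy matches the stationary fractions within 1%", {
  r <- demo_rates()
  occ <- simulate_occupancy(r, t_total = 400, seed = 13)
  expect_true(all(abs(occ - steady_state_fractions(r)) < 0.01))
})

test_that("the burn-in leaves the localisation law unchanged (stationary start)", {
  r <- demo_rates()
  ge <- cell_geometry()
  im_full <- imaging_config(equilibration = 0.2)
  im_none <- imaging_config(equilibration = 0)
  h1 <- build_histogram(track_dstars(
    simulate_ensemble(20000, r, state_diffusion(), im_full, ge, seed = 21,
                      keep_locs = FALSE)), im_full)
  h2 <- build_histogram(track_dstars(
    simulate_ensemble(20000, r, state_diffusion(), im_none, ge, seed = 22,
                      keep_locs = FALSE)), im_none)
  pooled <- h1$counts + h2$counts
  keep <- pooled >= 10
  chi2 <- sum((h1$counts[keep] - h2$counts[keep])^2 /
              (h1$counts[keep] + h2$counts[keep]))
  p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("mixture ensembles respect the species ratio and bound mobility", {
  r <- demo_rates()
  im <- fast_imaging()
  ge <- cell_geometry()
  ts <- simulate_mixture_ensemble(20000, 0.3, r, state_diffusion(), im, ge,
                                  seed = 14, keep_locs = FALSE)
  p_hat <- mean(ts$info$species == "bound")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
  # all-bound ensemble: mean D* ~ D_Target + sigma^2/dt, minus confinement
  tsb <- simulate_mixture_ensemble(20000, 1, r, state_diffusion(), im, ge,
                                   seed = 15, keep_locs = FALSE)
  m <- mean(track_dstars(tsb))
  expect_gt(m, 0.27)
  expect_lt(m, 0.34)
  # fraction 0 is identical in law (same seed => identical tracks)
  t0 <- simulate_mixture_ensemble(500, 0, r, state_diffusion(), im, ge,
                                  seed = 16)
  t1 <- simulate_ensemble(500, r, state_diffusion(), im, ge, seed = 16)
  expect_identical(t0$locs, t1$locs)
})
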