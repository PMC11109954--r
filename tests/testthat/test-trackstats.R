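test_that("the D* estimator implements the short-track MSD form", {
  expect_equal(estimate_dstar(data.frame(x = c(1, 1, 1), y = c(2, 2, 2),
                                         frame = 1:3), 0.01), 0)
  expect_equal(estimate_dstar(data.frame(x = c(0, 0.1), y = c(0, 0),
                                         frame = 1:2), 0.01), 0.25)
  tr <- data.frame(x = c(0, 0.1, 0.1), y = c(0, 0, 0.2), frame = 5:7)
  expect_equal(estimate_dstar(tr, 0.01), (0.01 + 0.04) / 2 / 0.04)
  # invariance under global translation and rotation
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(tr[, c("x", "y")]) %*% rot
  tr2 <- data.frame(x = xy[, 1] + 3, y = xy[, 2] - 1, frame = 5:7)
  expect_equal(estimate_dstar(tr2, 0.01), estimate_dstar(tr, 0.01))
  expect_error(estimate_dstar(data.frame(x = 1, y = 1, frame = 1), 0.01),
               "at least 2")
  expect_error(estimate_dstar(data.frame(x = 1:10, y = 1:10, frame = 1:10),
                              0.01), "longer than 9")
  expect_error(estimate_dstar(data.frame(x = 1:3, y = 1:3,
                                         frame = c(1, 3, 4)), 0.01),
               "consecutive")
})

test_that("pure-noise tracks average to sigma^2 / dt", {
  sigma <- 0.035; dt <- 0.01
  set.seed(31)
  d <- replicate(2e4, {
    estimate_dstar(data.frame(x = rnorm(3, 0, sigma), y = rnorm(3, 0, sigma),
                              frame = 1:3), dt)
  })
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - sigma^2 / dt), 3 * se)
})

test_that("histograms use 85 log bins with count-conserving edge clamps", {
  im <- imaging_config()
  h0 <- build_histogram(numeric(0), im)
  expect_equal(sum(h0$counts), 0)
  expect_equal(h0$n_tracks, 0)
  expect_length(h0$bin_edges, 86)
  h1 <- build_histogram(0.04, im)
  expect_equal(h1$counts[1], 1)
  # clamping conserves counts
  h <- build_histogram(c(1e-5, 0.2, 50), im)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$counts[1], 1)
  expect_equal(h$counts[85], 1)
  # log-uniform input spreads evenly over bins
  set.seed(32)
  hu <- build_histogram(10^runif(2e4, log10(0.04), 1), im)
  expect_gt(suppressWarnings(chisq.test(hu$counts)$p.value), 0.01)
  expect_equal(histogram_centers(h)[1], sqrt(h$bin_edges[1] * h$bin_edges[2]))
})

test_that("histogram CSV round trip preserves binning and counts", {
  im <- imaging_config()
  set.seed(33)
  h <- build_histogram(10^runif(500, log10(0.05), 0.5), im)
  path <- tempfile(fileext = ".csv")
  write_histogram(h, path)
  back <- read_histogram(path)
  expect_equal(back$counts, h$counts)
  expect_equal(back$n_tracks, h$n_tracks)
  expect_equal(back$bin_edges, h$bin_edges, tolerance = 1e-6)
})

test_that("linking reconstructs isolated emitters and rejects bad input", {
  # one emitter, small displacements: one track with all localisations
  t1 <- data.frame(frame = 1:5, x = cumsum(c(0, rep(0.1, 4))), y = rep(0, 5))
  ts <- link_localisations(t1, max_jump = 0.8)
  expect_equal(n_tracks(ts), 1)
  expect_equal(nrow(ts$locs), 5)
  expect_equal(ts$info$dstar, 0.1^2 / (4 * 0.01))
  # two simultaneous emitters far apart never merge
  t2 <- rbind(data.frame(frame = 1:3, x = 0, y = 0),
              data.frame(frame = 1:3, x = 3, y = 3))
  ts2 <- link_localisations(t2, max_jump = 0.8)
  expect_equal(n_tracks(ts2), 2)
  expect_true(all(ts2$info$length == 2))
  # a track growing beyond 9 localisations is discarded
  t3 <- data.frame(frame = 1:12, x = 0, y = 0)
  t3$x <- t3$x + (1:12) * 0.01
  expect_equal(n_tracks(link_localisations(t3, max_jump = 0.8)), 0)
  expect_error(link_localisations(rbind(t1, t1[1, ]), max_jump = 0.8),
               "duplicate")
})

test_that("re-linking synthetic data recovers the generator's tracks", {
  expt <- generate_experiment(demo_rates(), state_diffusion(), fast_imaging(),
                              cell_geometry(), n_cells = 30, seed = 34)
  ts <- link_localisations(expt$table, max_jump = 0.8)
  expect_equal(n_tracks(ts), nrow(expt$tracks$info))
  d_link <- sort(track_dstars(ts))
  d_true <- sort(track_dstars(expt$tracks))
  match_frac <- mean(abs(d_link - d_true) < 1e-9)
  expect_gte(match_frac, 0.99)
})

test_that("cells are grouped by track count with exclusion reporting", {
  info <- data.frame(track = 1:4, length = 3, cell_id = c(1, 1, 2, 3),
                     dstar = 0.2)
  info <- info[c(rep(1, 7), rep(3, 150), rep(4, 6)), ]
  info$track <- seq_len(nrow(info))
  ts <- mcdda:::new_track_set(NULL, info, imaging_config())
  g <- group_cells_by_track_count(ts)
  expect_named(g, c("7-50", "101-150"))
  expect_equal(attr(g, "excluded"), "3")          # 6 tracks: below all ranges
  expect_equal(unique(g[["7-50"]]$info$cell_id), 1)
  expect_equal(unique(g[["101-150"]]$info$cell_id), 2)  # 150 -> upper edge
  expect_error(group_cells_by_track_count(ts, list(c(7, 50), c(40, 80))),
               "overlap")
})

test_that("mean D* by track length pools lengths of 8 and above", {
  info <- data.frame(track = 1:8, length = c(2, 3, 3, 5, 8, 9, 10, 7),
                     cell_id = 1,
                     dstar = c(9, 0.5, 0.7, 0.4, 0.3, 0.2, 0.4, 0.6))
  ts <- mcdda:::new_track_set(NULL, info, imaging_config())
  tab <- mean_dstar_by_length(ts)
  expect_equal(tab$length, c("3", "5", "7", ">=8"))  # 4 and 6 empty: omitted
  expect_equal(tab$n[tab$length == ">=8"], 3)
  expect_equal(tab$mean_dstar[tab$length == "3"], 0.6)
  expect_equal(tab$se[tab$length == "5"], 0)
  # identical D* everywhere: zero standard errors
  info2 <- data.frame(track = 1:6, length = rep(c(3, 4, 8), 2), cell_id = 1,
                      dstar = 0.42)
  tab2 <- mean_dstar_by_length(mcdda:::new_track_set(NULL, info2,
                                                     imaging_config()))
  expect_true(all(tab2$mean_dstar == 0.42))
  expect_true(all(tab2$se == 0))
})

test_that("simulated mean D* decreases with track length for searcher kinetics", {
  ts <- simulate_ensemble(40000, demo_rates(), state_diffusion(),
                          fast_imaging(), cell_geometry(), seed = 35,
                          keep_locs = FALSE)
  tab <- mean_dstar_by_length(ts)
  # non-increasing trend within standard error slack
  expect_true(all(diff(tab$mean_dstar) < 3 * tab$se[-1] + 0.02))
  expect_lt(tab$mean_dstar[nrow(tab)], tab$mean_dstar[1])
})
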