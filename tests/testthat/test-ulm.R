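test_that("optimal assignment matches brute-force enumeration", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(1:5, 1)
    C <- matrix(runif(n * n), n, n)
    perm <- fusulm:::solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), perm)]), brute_assignment(C)$cost,
                 tolerance = 1e-10)
  }
  # with forbidden (Inf) entries, provided a feasible matching exists
  C <- matrix(c(1, Inf, Inf, 1, 5, 2, 3, 2, 1), 3, 3)
  perm <- fusulm:::solve_assignment(C)
  expect_true(all(is.finite(C[cbind(1:3, perm)])))
  Cf <- C; Cf[!is.finite(Cf)] <- 1e6
  expect_equal(sum(C[cbind(1:3, perm)]), brute_assignment(Cf)$cost)
})

test_that("bubble detection finds strict maxima and refines sub-pixel", {
  zc <- (1:32 - 0.5) * 0.1; xc <- (1:32 - 0.5) * 0.1
  blob <- function(z0, x0, a = 1, s = 0.045) {
    a * outer(exp(-(zc - z0)^2 / (2 * s^2)), exp(-(xc - x0)^2 / (2 * s^2)))
  }
  # single off-grid Gaussian: localization within 0.1 pixel
  img <- blob(1.234, 2.071)
  loc <- detect_bubbles(img, 0.1, 3, 0.1, 0.1)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$z_mm - 1.234), 0.01)
  expect_lt(abs(loc$x_mm - 2.071), 0.01)

  # blank frame
  expect_equal(nrow(detect_bubbles(matrix(0, 32, 32), 0.1, 3, 0.1, 0.1)), 0)

  # 9 well-separated blobs, 3 below threshold -> exactly 6, within 0.25 px
  centers <- expand.grid(z = c(0.8, 1.6, 2.4), x = c(0.8, 1.6, 2.4))
  amps <- c(1, 0.9, 0.05, 0.8, 0.04, 1.2, 0.06, 0.7, 1.1)
  img9 <- Reduce(`+`, lapply(1:9, function(i) blob(centers$z[i], centers$x[i], amps[i])))
  loc9 <- detect_bubbles(img9, 0.2, 3, 0.1, 0.1)
  expect_equal(nrow(loc9), 6)
  kept <- centers[amps >= 0.2, ]
  for (i in seq_len(nrow(kept))) {
    d <- sqrt((loc9$z_mm - kept$z[i])^2 + (loc9$x_mm - kept$x[i])^2)
    expect_lt(min(d), 0.025)
  }

  # centroid mode stays within a quarter pixel too
  locc <- detect_bubbles(img, 0.1, 3, 0.1, 0.1, refine = "centroid")
  expect_lt(abs(locc$z_mm - 1.234), 0.025)

  expect_error(detect_bubbles(matrix(1, 4, 4), 0.1, neighborhood = 9), "larger")
})

test_that("a bubble on a pixel boundary is detected exactly once", {
  zc <- (1:16 - 0.5) * 0.1; xc <- (1:16 - 0.5) * 0.1
  img <- outer(exp(-(zc - 0.8)^2 / (2 * 0.045^2)),   # z on a boundary
               exp(-(xc - 0.75)^2 / (2 * 0.045^2)))  # x on a centre
  loc <- detect_bubbles(img, 0.1, 3, 0.1, 0.1)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$z_mm - 0.8), 0.01)
})

test_that("linking: continuity, gating, and optimality against brute force", {
  # one bubble per frame for 10 frames -> one track of 10 points
  locs <- tibble::tibble(frame = 1:10, z_mm = 1, x_mm = 0.1 * (1:10),
                         intensity = 1)
  tr <- link_tracks(locs, max_link_mm = 0.15, min_length = 4)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 10)

  # displacement beyond the gate: no link (two fragments, dropped by length)
  locs2 <- tibble::tibble(frame = rep(1:8, 1), z_mm = 1,
                          x_mm = c(0.1 * (1:4), 2 + 0.1 * (1:4)))
  tr2 <- link_tracks(locs2, max_link_mm = 0.15, min_length = 4)
  expect_equal(dplyr::n_distinct(tr2$track_id), 2)
  expect_true(all(table(tr2$track_id) == 4))

  # two crossing bubbles, small steps: assignment equals exhaustive matching
  fr <- 1:9
  a <- cbind(z = 1 + 0.02 * fr, x = 1 + 0.02 * fr)
  b <- cbind(z = 1.4 - 0.02 * fr, x = 1 + 0.02 * fr)
  locs3 <- tibble::tibble(frame = rep(fr, 2),
                          z_mm = c(a[, 1], b[, 1]), x_mm = c(a[, 2], b[, 2]))
  tr3 <- link_tracks(locs3, max_link_mm = 0.08, min_length = 4)
  expect_equal(dplyr::n_distinct(tr3$track_id), 2)
  # each recovered track is one of the true bubbles throughout
  for (id in unique(tr3$track_id)) {
    pts <- dplyr::arrange(tr3[tr3$track_id == id, ], frame)
    steps <- sqrt(diff(pts$z_mm)^2 + diff(pts$x_mm)^2)
    expect_true(all(steps < 0.08))
    expect_equal(nrow(pts), 9)
  }

  # empty input
  tr0 <- link_tracks(tibble::tibble(frame = integer(), z_mm = numeric(),
                                    x_mm = numeric()), 0.1)
  expect_equal(nrow(tr0), 0)
})

test_that("gap closing links across a missed frame only when enabled", {
  locs <- tibble::tibble(frame = c(1:4, 6:9), z_mm = 1,
                         x_mm = 0.01 * c(1:4, 6:9))
  tr_nogap <- link_tracks(locs, max_link_mm = 0.015, min_length = 4)
  expect_equal(dplyr::n_distinct(tr_nogap$track_id), 2)
  tr_gap <- link_tracks(locs, max_link_mm = 0.015, min_length = 4, max_gap = 1)
  expect_equal(dplyr::n_distinct(tr_gap$track_id), 1)
})

test_that("track velocities: arithmetic, signs and antisymmetry", {
  # 10 um steps at 1000 Hz -> 10 mm/s
  tr <- tibble::tibble(track_id = 1L, frame = 1:5, z_mm = 0.01 * (0:4) + 1,
                       x_mm = 1)
  class(tr) <- c("fus_tracks", class(tibble::tibble()))
  tv <- track_velocities(tr, 1000)
  expect_equal(tv$speed[1:4], rep(10, 4))
  expect_equal(tv$vx[1:4], rep(0, 4))
  expect_true(all(tv$vz[1:4] > 0))          # descending: z positive downward
  expect_true(is.na(tv$speed[5]))

  # reversing the point order negates every segment velocity
  rev_tr <- tr
  rev_tr$z_mm <- rev(tr$z_mm)
  rv <- track_velocities(rev_tr, 1000)
  expect_equal(rv$vz[1:4], -tv$vz[1:4])

  expect_error(track_velocities(tibble::tibble(track_id = 1, frame = 1,
                                               z_mm = 0, x_mm = 0), 1000),
               "2 points")
})

test_that("super-resolved maps conserve counts and attribute speeds", {
  cfg <- config_ulm(n_blocks = 1, depth_mm = 0.65, width_mm = 0.65)
  # constant-velocity track: every visited pixel carries that speed
  tr <- tibble::tibble(track_id = 1L, frame = 1:20,
                       z_mm = seq(0.1, 0.5, length.out = 20),
                       x_mm = seq(0.1, 0.5, length.out = 20))
  class(tr) <- c("fus_tracks", class(tibble::tibble()))
  tv <- track_velocities(tr, 1000)
  maps <- render_maps(tv, cfg, pitch_um = 6.5)
  expect_equal(dim(maps$density), c(100L, 100L))   # ceil(0.65 / 0.0065)
  expect_equal(sum(maps$density), 20)              # conservation
  sp <- unique(round(maps$speed[!is.na(maps$speed)], 9))
  expect_equal(sp, round(tv$speed[1], 9))

  # n localizations in one pixel
  tr2 <- tibble::tibble(track_id = 1L, frame = 1:5, z_mm = 0.101, x_mm = 0.101)
  class(tr2) <- c("fus_tracks", class(tibble::tibble()))
  tv2 <- suppressWarnings(track_velocities(tr2, 1000))
  m2 <- render_maps(tv2, cfg)
  expect_equal(max(m2$density), 5L)
  expect_equal(sum(m2$density), 5L)

  # empty tracks: zero-count maps, no error
  tr0 <- tibble::tibble(track_id = integer(), frame = integer(),
                        z_mm = numeric(), x_mm = numeric(),
                        vz = numeric(), vx = numeric(), speed = numeric())
  class(tr0) <- c("fus_tracks", class(tibble::tibble()))
  m0 <- render_maps(tr0, cfg)
  expect_equal(sum(m0$density), 0L)
})

test_that("tracking is deterministic under identical input", {
  set.seed(77)
  locs <- tibble::tibble(frame = rep(1:20, each = 3),
                         z_mm = runif(60, 1, 2), x_mm = runif(60, 1, 2))
  t1 <- link_tracks(locs, 0.2, min_length = 2)
  t2 <- link_tracks(locs, 0.2, min_length = 2)
  expect_identical(t1, t2)
})

test_that("end-to-end: dilute noise-free movie is tracked at the stated accuracy", {
  cfg <- config_ulm(n_blocks = 8, depth_mm = 6.4, width_mm = 6.4)
  vessels <- default_vessels(cfg, c(10, 15, 20))
  sim <- simulate_bubble_stack(cfg, vessels, bubbles_per_frame = 0.001,
                               tissue_rank = 0, noise_db = -Inf, seed = 11)
  locs <- ulm_localize(sim$stack, min_intensity = 0.1, n_remove = 0)
  tr <- track_velocities(
    link_tracks(locs, max_link_mm = 1.5 * 20 / cfg$framerate, min_length = 4),
    cfg$framerate)
  m <- match_segments(tr, sim$truth$tracks)
  expect_gt(sum(m$err < 0.05, na.rm = TRUE) / m$n_truth, 0.9)
  # per-track mean speeds land on the simulated 10/15/20 mm/s
  tsum <- tidy(tr)
  tsum <- tsum[tsum$n_points >= 20, ]
  nearest <- sapply(tsum$mean_speed, function(s) min(abs(s - c(10, 15, 20)) / c(10, 15, 20)))
  expect_lt(stats::median(nearest), 0.05)
})
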