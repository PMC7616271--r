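make_series <- function(xyz) {
  m <- matrix(unlist(xyz), ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

test_that("trial clipping keeps exactly the trial window", {
  rec <- trial_record("d", TRUE, FALSE, 1, fps = 24, duration = 120)
  n_rec <- 3000
  coords <- list(head_centre = cbind(seq(0, 1, length.out = n_rec), 0, 0.5))
  traj <- kp_trajectory(0:(n_rec - 1), coords)
  clipped <- clip_to_trial(traj, rec, onset = 60)
  expect_equal(length(clipped$frames), 2880)
  expect_equal(clipped$frames[1], 0L)
  expect_equal(clipped$coords$head_centre[1, 1],
               coords$head_centre[61, 1], ignore_attr = TRUE)

  # onset 0 with exactly the right length is the identity
  traj2 <- kp_trajectory(0:2879, list(head_centre = cbind(0, 0, 0.5)[rep(1, 2880), ]))
  clipped2 <- clip_to_trial(traj2, rec, onset = 0)
  expect_equal(clipped2$coords$head_centre, traj2$coords$head_centre)

  # a recording entirely before the onset is an error
  traj3 <- kp_trajectory(0:99, list(head_centre = cbind(0, 0, 0.5)[rep(1, 100), ]))
  expect_error(clip_to_trial(traj3, rec, onset = 500), "does not overlap")
})

test_that("bounds filter removes out-of-room and too-high points, strictly", {
  geom <- room_geometry()
  m <- make_series(list(c(0, 0, 1.6),      # too high -> removed
                        c(0, 0, 1.5),      # exactly at the cap -> kept
                        c(10, 0, 0.5),     # outside the room -> removed
                        c(0, 0, 0.5)))
  fb <- filter_bounds(m, geom)
  expect_equal(unname(which(fb$removed)), c(1, 3))
  expect_false(anyNA(fb$m[c(2, 4), ]))
})

test_that("centroid filter removes single displaced key points", {
  # seven key points at the origin and one at (2, 0, 0): the mean is
  # (0.25, 0, 0), the displaced point is 1.75 m from it, the rest 0.25 m
  coords <- setNames(lapply(1:8, function(i) {
    if (i == 1) matrix(c(2, 0, 0), 1) else matrix(c(0, 0, 0), 1)
  }), keypoint_names())
  fc <- filter_centroid_outliers(coords)
  expect_true(fc$removed[[1]])
  expect_false(any(unlist(fc$removed[-1])))

  # all key points coincident: nothing removed
  coords2 <- setNames(lapply(1:8, function(i) matrix(c(1, 1, 0.3), 1)),
                      keypoint_names())
  expect_false(any(unlist(filter_centroid_outliers(coords2)$removed)))

  # a deviation of exactly the threshold is kept ("more than" is strict);
  # two points 2 m apart each sit exactly 1 m from their mean
  coords3 <- list(snout = matrix(c(2, 0, 0), 1),
                  hips = matrix(c(0, 0, 0), 1))
  expect_false(any(unlist(filter_centroid_outliers(coords3)$removed)))

  # a frame with a single detection is never removed
  coords4 <- list(snout = matrix(c(50, 50, 0), 1))
  expect_false(any(unlist(filter_centroid_outliers(coords4)$removed)))
})

test_that("neighbour-jump filter removes spikes but keeps their neighbours", {
  smooth <- cbind(seq(0, 1, by = 0.05), 0, 0.5)
  expect_equal(sum(filter_neighbour_jumps(smooth)$removed), 0)

  spiked <- smooth
  spiked[10, 1] <- spiked[10, 1] + 2
  fj <- filter_neighbour_jumps(spiked)
  expect_equal(unname(which(fj$removed)), 10)

  # a length-one series has no neighbour evidence and is kept
  one <- matrix(c(0, 0, 0.5), 1)
  expect_equal(sum(filter_neighbour_jumps(one)$removed), 0)

  # strict-OR semantics delete both endpoints of a genuine 2 m step
  stepped <- cbind(c(rep(0, 5), rep(2, 5)), 0, 0.5)
  cfg <- filter_config(neighbour_mode = "strict")
  expect_equal(unname(which(filter_neighbour_jumps(stepped, cfg)$removed)),
               c(5, 6))
  # ...while spike semantics keep them (each agrees with one neighbour)
  expect_equal(sum(filter_neighbour_jumps(stepped)$removed), 0)
})

test_that("linear interpolation fills interior gaps and never extrapolates", {
  m <- make_series(list(c(0, 0, 0), c(NA, NA, NA), c(NA, NA, NA),
                        c(0.3, 0, 0)))
  ip <- interpolate_gaps(m)
  expect_equal(ip$m[2, 1], 0.1, ignore_attr = TRUE)
  expect_equal(ip$m[3, 1], 0.2, ignore_attr = TRUE)
  expect_equal(which(ip$filled), c(2, 3))

  # no gaps: identity with an empty mask
  full <- cbind(1:5 / 10, 0, 0.5)
  ip2 <- interpolate_gaps(full)
  expect_equal(ip2$m, full)
  expect_false(any(ip2$filled))

  # a leading gap stays missing
  lead <- full
  lead[1:2, ] <- NA
  ip3 <- interpolate_gaps(lead)
  expect_true(all(is.na(ip3$m[1:2, 1])))

  # all-missing series is returned unchanged with a warning
  allna <- matrix(NA_real_, 4, 3)
  expect_warning(ip4 <- interpolate_gaps(allna), "entirely missing")
  expect_true(all(is.na(ip4$m)))

  # max_gap limits which gaps are bridged
  gappy <- cbind(c(0, NA, NA, NA, 0.4, NA, 0.6), 0, 0.5)
  cfg <- filter_config(max_gap = 1)
  ip5 <- interpolate_gaps(gappy, cfg)
  expect_true(all(is.na(ip5$m[2:4, 1])))
  expect_equal(ip5$m[6, 1], 0.5)
})

test_that("iterated velocity filter removes fast steps and re-interpolates", {
  cfg <- filter_config()
  # the per-frame threshold corresponds to 9.6 m/s at 24 fps
  expect_equal(cfg$velocity_step * cfg$fps, 9.6)

  const <- cbind(rep(0.3, 20), 0, 0.5)
  fv <- filter_velocity_iterative(const, rep(1L, 20), cfg)
  expect_equal(sum(fv$removed_detections), 0)

  # an isolated 1 m x-displacement at frame 11 (0-based: 10 -> 11)
  smooth <- cbind(seq(0, 1.9, by = 0.1), 0, 0.5)
  spiked <- smooth
  spiked[12, 1] <- spiked[12, 1] + 1
  st <- rep(1L, 20)
  fv2 <- filter_velocity_iterative(spiked, st, cfg)
  expect_true(fv2$removed_detections[1] >= 1)
  expect_equal(fv2$status[12], 2L)        # re-interpolated, not retained
  d <- abs(diff(fv2$m[, 1]))
  expect_true(all(d[!is.na(d)] <= 0.4 + 1e-12))
})

test_that("rolling average smooths with a shrinking window at the edges", {
  const <- cbind(rep(2, 10), 1, 0.5)
  expect_equal(smooth_rolling(const), const, ignore_attr = TRUE)

  tri <- cbind(c(0, 0.3, 0), 0, 0.5)
  sm <- smooth_rolling(tri)
  expect_equal(sm[2, 1], 0.1)
  expect_equal(sm[1, 1], 0.15)   # window shrinks to frames 1-2

  ramp <- cbind(seq(0, 1, length.out = 11), 0, 0.5)
  sm2 <- smooth_rolling(ramp)
  expect_equal(sm2[2:10, 1], ramp[2:10, 1])  # linearity preserved inside
})

test_that("a noiseless trial passes through the cascade with zero loss", {
  rec <- short_record(duration = 20)
  st <- simulate_trial(rec, seed = 41)
  pp <- preprocess_trial(st$traj, rec)
  expect_equal(sum(pp$ledger$removed), 0)
  expect_true(all(pp$prop_tracked == 1))
  # smoothing only perturbs the trajectory at the curvature scale
  dev <- max(abs(pp$coords$head_centre - st$traj$coords$head_centre))
  expect_lt(dev, 0.05)
})

test_that("the cascade removes injected corruption and conserves counts", {
  rec <- short_record(duration = 60)
  st <- simulate_trial(rec, seed = 42)
  cr <- corrupt(st$traj, noise_params(), seed = 43)
  pp <- preprocess_trial(cr$traj, rec)

  corr <- cr$corruption[cr$corruption$channel != "dropout", ]
  gone <- mapply(function(kp, f) pp$status[[kp]][f + 1] != 1L,
                 corr$keypoint, corr$frame)
  expect_gte(mean(gone), 0.95)

  for (kp in keypoint_names()) {
    n_in <- pp$n_input[[kp]]
    retained <- sum(pp$status[[kp]] == 1L)
    removed <- sum(pp$ledger$removed[pp$ledger$keypoint == kp])
    expect_equal(n_in, retained + removed)
  }

  # all retained detections satisfy the bounds filter
  geom <- room_geometry()
  for (kp in keypoint_names()) {
    kept <- pp$status[[kp]] == 1L
    m <- pp$coords[[kp]][kept, , drop = FALSE]
    expect_true(all(m[, 1] >= geom$floor[1] & m[, 1] <= geom$floor[2] &
                    m[, 2] >= geom$floor[3] & m[, 2] <= geom$floor[4] &
                    m[, 3] <= geom$height_cap))
  }

  # after the final iteration every within-span step obeys the threshold or
  # involves an interpolated frame bridging an original gap
  for (kp in keypoint_names()) {
    m <- pp$coords[[kp]]
    s <- pp$status[[kp]]
    d <- abs(diff(m))
    viol <- which(!is.na(d[, 1]) &
                  (d[, 1] > 0.4 | d[, 2] > 0.4 | d[, 3] > 0.4))
    # smoothing happens after the last velocity pass, so allow for its
    # threefold averaging when attributing violations
    expect_true(all(s[viol] == 2L | s[viol + 1] == 2L))
  }
})

test_that("proportion tracked is simple count arithmetic", {
  rec <- trial_record("d", TRUE, FALSE, 1, fps = 24, duration = 120)
  st <- simulate_trial(rec, seed = 44)
  traj <- st$traj
  drop <- 101:388  # 288 frames of 2880
  traj$coords$head_centre[drop, ] <- NA_real_
  pp <- preprocess_trial(traj, rec)
  expect_equal(pp$prop_tracked[["head_centre"]], 0.9)
})

test_that("more corruption never removes fewer detections", {
  rec <- short_record(duration = 30)
  st <- simulate_trial(rec, seed = 45)
  totals <- vapply(c(0.002, 0.006, 0.02), function(rate) {
    cr <- corrupt(st$traj, noise_params(dropout = 0.02, teleport = rate,
                                        glitch = rate, jump = rate),
                  seed = 46)
    pp <- preprocess_trial(cr$traj, rec)
    sum(pp$ledger$removed)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("preprocessing is deterministic", {
  rec <- short_record(duration = 20)
  cr <- corrupt(simulate_trial(rec, seed = 47)$traj, noise_params(), seed = 48)
  a <- preprocess_trial(cr$traj, rec)
  b <- preprocess_trial(cr$traj, rec)
  expect_identical(a$coords, b$coords)
  expect_identical(a$ledger, b$ledger)
})
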