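test_that("interest-area occupancy follows the half-open rectangle rule", {
  rect <- c(0, 1, 0, 1)
  inside <- cbind(runif(20, 0.1, 0.9), runif(20, 0.1, 0.9), 0.5)
  expect_equal(time_in_area(inside, rect), 1)

  half <- rbind(inside[1:10, ],
                cbind(runif(10, 2, 3), runif(10, 2, 3), 0.5))
  expect_equal(time_in_area(half, rect), 0.5)

  edges <- rbind(c(0, 0.5, 0.5),   # on the lower edge: inside
                 c(1, 0.5, 0.5))   # on the upper edge: outside
  expect_equal(time_in_area(edges, rect), 0.5)

  expect_warning(na_val <- time_in_area(matrix(NA_real_, 3, 3), rect),
                 "zero coverage")
  expect_true(is.na(na_val))
})

test_that("distance travelled matches hand geometry and the naive oracle", {
  expect_equal(distance_travelled(cbind(1, 1, 0.5)[rep(1, 10), ]), 0)

  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(distance_travelled(square), 4)

  set.seed(71)
  for (i in 1:10) {
    m <- cbind(cumsum(rnorm(40, 0, 0.1)), cumsum(rnorm(40, 0, 0.1)),
               0.5 + cumsum(rnorm(40, 0, 0.02)))
    m[sample(40, 6), ] <- NA
    expect_equal(distance_travelled(m), oracle_distance(m), tolerance = 1e-9)
  }

  # time reversal leaves the distance unchanged
  m <- cbind(cumsum(rnorm(30, 0, 0.1)), cumsum(rnorm(30, 0, 0.1)), 0.5)
  expect_equal(distance_travelled(m), distance_travelled(m[30:1, ]),
               tolerance = 1e-12)
})

test_that("object distance matches symmetry cases and the naive oracle", {
  objects <- list(c(2, 0), c(-2, 0), c(0, 2), c(0, -2))
  centre <- cbind(0, 0, 0.5)
  expect_equal(min_object_distance(centre, objects), 2)

  over <- rbind(c(2, 0, 0.5), c(5, 5, 0.5))
  expect_equal(min_object_distance(over, list(c(2, 0))), 0)

  set.seed(72)
  for (i in 1:10) {
    m <- cbind(runif(30, -3, 3), runif(30, -3, 3), 0.5)
    m[sample(30, 4), ] <- NA
    expect_equal(min_object_distance(m, objects),
                 oracle_min_object_distance(m, objects), tolerance = 1e-9)
  }
})

test_that("area covered counts grid cells like the set-based oracle", {
  geom <- room_geometry()
  expect_equal(area_covered(cbind(0.1, 0.1, 0.5), geom), 1 / 168)

  # an exhaustive sweep through every cell centre covers everything
  centres <- expand.grid(x = seq(-2.75, 2.75, by = 0.5),
                         y = seq(-3.25, 3.25, by = 0.5))
  sweep_m <- cbind(centres$x, centres$y, 0.5)
  expect_equal(area_covered(sweep_m, geom), 1)

  set.seed(73)
  for (i in 1:10) {
    m <- cbind(runif(50, -3, 3), runif(50, -3.5, 3.5), 0.5)
    m[sample(50, 5), ] <- NA
    expect_equal(area_covered(m, geom), oracle_area_covered(m, geom),
                 tolerance = 1e-9)
  }
})

test_that("the 45-degree elevated gaze gives the stated angles", {
  head <- matrix(c(0, 0, 0.5), 1)
  snout <- matrix(c(0.2, 0, 0.5), 1)   # horizontal head axis along +x
  eye <- c(0.1, 0, 0.5)
  gaze <- c(cos(pi / 4), 0, sin(pi / 4))

  # a target straight down the elevated gaze: 0 degrees
  expect_equal(visual_angle_series(head, snout, eye + 2 * gaze), 0,
               tolerance = 1e-9)
  # a target ahead at eye height: the full 45-degree elevation
  expect_equal(visual_angle_series(head, snout, c(10, 0, 0.5)), 45,
               tolerance = 1e-9)
  # a target exactly behind the gaze: 180 degrees
  expect_equal(visual_angle_series(head, snout, eye - 2 * gaze), 180,
               tolerance = 1e-9)

  # coincident key points are skipped
  expect_true(is.na(visual_angle_series(head, head, c(1, 1, 1))))
  # a vertical head axis leaves the rotation plane undefined
  up <- matrix(c(0, 0, 0.9), 1)
  expect_true(is.na(visual_angle_series(head, up, c(1, 1, 1))))

  expect_equal(mean_visual_angle(c(45, 45)), 45)
  expect_equal(mean_visual_angle(c(0, 90, NA)), 45)
  expect_true(is.na(mean_visual_angle(c(NA_real_, NA_real_))))
})

test_that("visual angles stay in [0, 180] on simulated data", {
  st <- simulate_trial(short_record(), seed = 74)
  ang <- visual_angle_series(st$traj$coords$head_centre,
                             st$traj$coords$snout, c(-2.7, 0, 0.5))
  expect_true(all(ang >= 0 & ang <= 180, na.rm = TRUE))
})

test_that("tail-wag ratio is an arc-length quotient", {
  base <- cbind(seq(0, 10, length.out = 200), 0, 0.4)
  expect_equal(tail_wag_ratio(base, base), 1)

  tip <- base + cbind(0, 0.2 * sin(seq(0, 40, length.out = 200)), -0.05)
  expect_equal(tail_wag_ratio(tip, base),
               oracle_distance(tip) / oracle_distance(base),
               tolerance = 1e-9)
  expect_gt(tail_wag_ratio(tip, base), 1)

  still <- cbind(1, 1, 0.4)[rep(1, 50), ]
  expect_warning(r <- tail_wag_ratio(still, still), "did not move")
  expect_true(is.na(r))
})

test_that("tail angle is signed rightward-positive and mirror-antisymmetric", {
  # dog heading +x: atlas ahead of tail base; tail tip straight behind
  atlas <- matrix(c(0.25, 0, 0.5), 1)
  base <- matrix(c(-0.4, 0, 0.4), 1)
  tip_straight <- matrix(c(-0.7, 0, 0.35), 1)
  expect_equal(tail_angle_series(atlas, base, tip_straight), 0)

  # tip offset towards the dog's right (facing +x with z up: -y)
  tip_right <- matrix(c(-0.6, -0.2, 0.35), 1)
  expect_gt(tail_angle_series(atlas, base, tip_right), 0)

  # mirroring the scene through the body axis flips the sign exactly
  refl <- function(m) { m[, 2] <- -m[, 2]; m }
  expect_equal(tail_angle_series(refl(atlas), refl(base), refl(tip_right)),
               -tail_angle_series(atlas, base, tip_right))

  # heading-independence: rotate the whole configuration arbitrarily
  th <- 1.234
  rot <- function(m) cbind(cos(th) * m[, 1] - sin(th) * m[, 2],
                           sin(th) * m[, 1] + cos(th) * m[, 2], m[, 3])
  expect_equal(tail_angle_series(rot(atlas), rot(base), rot(tip_right)),
               tail_angle_series(atlas, base, tip_right), tolerance = 1e-9)

  # degenerate projections are skipped
  expect_true(is.na(tail_angle_series(atlas, base, base)))
})

test_that("mean tail angle recovers bias and symmetric wags cancel", {
  n <- 2400
  t <- seq_len(n)
  phi <- 30 * sin(2 * pi * 2.5 * t / 24)  # whole periods over the window
  atlas <- cbind(0.25, 0, 0.5)[rep(1, n), ]
  base <- cbind(-0.4, 0, 0.4)[rep(1, n), ]
  tip <- cbind(-0.4 - 0.3 * cos(phi * pi / 180),
               -0.3 * sin(phi * pi / 180), 0.35)
  ang <- tail_angle_series(atlas, base, tip)
  expect_lt(abs(mean_tail_angle(ang)), 1e-6)

  expect_equal(mean_tail_angle(rep(30, 5)), 30)

  # per-frame angles stay inside (-180, 180]
  st <- simulate_trial(short_record(), seed = 75)
  ang2 <- tail_angle_series(st$traj$coords$atlas, st$traj$coords$tail_base,
                            st$traj$coords$tail_tip)
  expect_true(all(ang2 > -180 & ang2 <= 180, na.rm = TRUE))
})

test_that("trial metrics assemble correctly for a confined trajectory", {
  geom <- room_geometry()
  rec <- short_record()
  # shrink the trajectory and park it inside the owner IA (chair A)
  st <- simulate_trial(rec, seed = 76)
  traj <- st$traj
  cx <- mean(traj$coords$head_centre[, 1])
  cy <- mean(traj$coords$head_centre[, 2])
  traj$coords <- lapply(traj$coords, function(m) {
    cbind(-2.3 + 0.1 * (m[, 1] - cx), 0.1 * (m[, 2] - cy), m[, 3])
  })
  met <- compute_trial_metrics(traj, geom, rec)
  expect_equal(met$prop_owner_ia, 1)
  expect_equal(met$prop_stranger_ia, 0)
  expect_lte(met$prop_owner_ia + met$prop_stranger_ia + met$prop_door_ia, 1)
})

test_that("metrics are invariant to rigid motions of the whole scene", {
  geom <- room_geometry()
  rec <- short_record()
  st <- simulate_trial(rec, seed = 77)
  ref <- compute_trial_metrics(st$traj, geom, rec)
  vars <- c("prop_owner_ia", "prop_stranger_ia", "prop_door_ia",
            "distance_travelled", "min_object_distance", "area_covered",
            "mean_visual_angle", "tail_wag_ratio", "mean_tail_angle")
  for (k in 1:3) {
    shift <- c(1.37, -0.83)
    m2 <- compute_trial_metrics(transform_traj(st$traj, k, shift),
                                transform_geometry(geom, k, shift), rec)
    for (v in vars) expect_equal(m2[[v]], ref[[v]], tolerance = 1e-9,
                                 label = sprintf("%s (k=%d)", v, k))
  }

  # mirror reflection negates the mean tail angle and preserves the rest
  mm <- compute_trial_metrics(mirror_traj(st$traj), mirror_geometry(geom), rec)
  expect_equal(mm$mean_tail_angle, -ref$mean_tail_angle, tolerance = 1e-9)
  for (v in setdiff(vars, "mean_tail_angle"))
    expect_equal(mm[[v]], ref[[v]], tolerance = 1e-9, label = v)
})
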