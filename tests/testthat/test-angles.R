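test_that("declination follows the plantarward-positive convention", {
  horiz <- foot_line(c(0, 0), c(1, 0))
  expect_equal(declination(horiz), 0)
  th <- 20 * pi / 180
  expect_equal(declination(foot_line(c(0, 0), c(cos(th), sin(th)))), 20,
               tolerance = 1e-9)
  expect_equal(declination(foot_line(c(0, 0), c(cos(th), -sin(th)))), -20,
               tolerance = 1e-9)

  # antisymmetry over random direction pairs
  set.seed(1)
  for (i in 1:50) {
    a <- foot_line(c(0, 0), c(cos(runif(1, -1.2, 1.2)),
                              sin(runif(1, -1.2, 1.2))))
    b <- foot_line(c(0, 0), c(cos(runif(1, -1.2, 1.2)),
                              sin(runif(1, -1.2, 1.2))))
    expect_equal(declination(a, b), -declination(b, a), tolerance = 1e-9)
  }
})

test_that("Meary angle is metatarsal minus talar declination", {
  mk <- function(deg) {
    th <- deg * pi / 180
    foot_line(c(0, 0), c(cos(th), sin(th)))
  }
  expect_equal(meary_angle(mk(20), mk(10)), -10, tolerance = 1e-9)
  expect_equal(meary_angle(mk(12), mk(12)), 0, tolerance = 1e-9)
  expect_equal(meary_angle(mk(20), mk(10), sign_flip = TRUE), 10,
               tolerance = 1e-9)
})

test_that("calcaneal pitch is the acute angle to the weightbearing line", {
  mk <- function(deg) {
    th <- deg * pi / 180
    foot_line(c(0, 0), c(cos(th), sin(th)))
  }
  expect_equal(calcaneal_pitch(mk(-22), mk(0)), 22, tolerance = 1e-9)
  expect_equal(calcaneal_pitch(mk(5), mk(5)), 0, tolerance = 1e-9)
  # co-rotating both lines leaves the pitch unchanged
  expect_equal(calcaneal_pitch(mk(-22 + 7), mk(7)), 22, tolerance = 1e-9)
  # non-physiologic tilt still yields the acute magnitude, with warning
  expect_warning(p <- calcaneal_pitch(mk(15), mk(0)), "below")
  expect_equal(p, 15, tolerance = 1e-9)
})

test_that("classification cutoffs are strict inequalities", {
  expect_false(classify_pp(-4, 25)$pp_by_meary)
  expect_true(classify_pp(-4.01, 25)$pp_by_meary)
  expect_false(classify_pp(0, 18)$pp_by_pitch)
  expect_true(classify_pp(0, 17.99)$pp_by_pitch)
  expect_error(classify_pp(NaN, 20), "finite")

  # monotone: decreasing an angle never flips PP back to non-PP
  sweep <- seq(5, -25, by = -0.25)
  flags <- vapply(sweep, function(m) classify_pp(m, 25)$pp_by_meary,
                  logical(1))
  expect_true(all(diff(flags) >= 0))
  sweep_p <- seq(40, 1, by = -0.25)
  flags_p <- vapply(sweep_p, function(p) classify_pp(0, p)$pp_by_pitch,
                    logical(1))
  expect_true(all(diff(flags_p) >= 0))
})

test_that("measure_foot recovers generator truth and classifies it", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 1))
  m <- measure_foot(s$mask)
  expect_gt(m$meary, -11.5); expect_lt(m$meary, -8.5)
  expect_gt(m$pitch, 21); expect_lt(m$pitch, 23)
  expect_true(m$pp_by_meary)
  expect_false(m$pp_by_pitch)
  expect_equal(m$landmark_source, "automatic")

  expect_error(measure_foot(matrix(0L, 300, 300)), "absent")
})

test_that("full manual override reproduces closed-form angles", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 1))
  pts <- s$landmarks$points
  m <- measure_foot(s$mask, overrides = pts)
  expect_equal(m$landmark_source, "manual")
  ang <- function(a, b) atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi
  meary_cf <- ang(pts$mt1_proximal_mid, pts$mt1_distal_mid) -
    ang(pts$talar_body_mid, pts$talar_neck_mid)
  pitch_cf <- abs(ang(pts$calc_tangent_posterior, pts$calc_tangent_anterior) -
                    ang(pts$wbs_posterior, pts$wbs_anterior))
  expect_equal(m$meary, meary_cf, tolerance = 0.2)
  expect_equal(m$pitch, pitch_cf, tolerance = 0.2)
})

test_that("angles are invariant to translation, scaling and rotation", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 5))
  base <- measure_foot(s$mask)

  tr <- measure_foot(translate_mask(s$mask, 15L, -10L))
  expect_lt(abs(tr$meary - base$meary), 0.1)
  expect_lt(abs(tr$pitch - base$pitch), 0.1)

  sc <- measure_foot(scale_mask(s$mask, 2))
  expect_lt(abs(sc$meary - base$meary), 0.1)
  expect_lt(abs(sc$pitch - base$pitch), 0.1)

  for (th in c(-10, 5)) {
    ro <- suppressWarnings(measure_foot(rotate_mask(s$mask, th)))
    expect_lt(abs(ro$meary - base$meary), 0.7)
    expect_lt(abs(ro$pitch - base$pitch), 0.7)
  }
})
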