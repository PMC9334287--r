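test_that("principal axis recovers rectangle orientation and tie-breaks", {
  m <- rect_mask()
  ax <- principal_axis(m, 1L)
  expect_equal(ax$direction, c(1, 0), tolerance = 1e-6)

  rot <- rotate_mask(m, 30)
  ax30 <- principal_axis(rot, 1L)
  expect_lt(abs(declination(ax30) - 30), 0.5)

  expect_equal(principal_axis(disk_mask(), 1L)$direction, c(1, 0))

  expect_error(principal_axis(m, 3L), "absent")
  tiny <- matrix(0L, 64, 64); tiny[30:32, 30:33] <- 1L
  expect_error(principal_axis(tiny, 1L), "fewer than")
})

test_that("width profile measures rectangle chords on the axis", {
  m <- rect_mask(y0 = 51, y1 = 70)   # height 20
  ax <- principal_axis(m, 1L)
  wp <- width_profile(m, 1L, ax, 51)
  expect_false(any(wp$empty))
  expect_true(all(abs(wp$width - 19) <= 1))
  expect_true(all(abs(wp$mid_y - 60.5) <= 0.6))
  expect_true(all(diff(wp$station) > 0))
  expect_error(width_profile(m, 1L, ax, 5), "n_stations")
})

test_that("width profile sees the metatarsal metaphyseal flares", {
  s <- generate_foot(foot_spec(15, 10, 22, rng_seed = 2))
  ax <- principal_axis(s$mask, 2L)
  wp <- width_profile(s$mask, 2L, ax, 101)
  mid <- wp$station >= 0.30 & wp$station <= 0.70
  w_min <- min(wp$width[mid])
  ends <- c(1, nrow(wp))   # outermost stations, deepest into the flares
  expect_true(all(wp$width[ends] >= 1.35 * w_min))
})

test_that("talar axis recovers the generated declination", {
  for (td in c(0, 8, 20, 33)) {
    s <- generate_foot(foot_spec(td, 8, 22, rng_seed = 30 + td))
    ta <- talar_axis(s$mask)
    expect_lt(abs(declination(ta$axis) - td), 1)
    expect_lt(ta$talar_body_mid[1], ta$talar_neck_mid[1])
  }
  no_talus <- generate_foot(foot_spec(12, 8, 22, rng_seed = 3))$mask
  no_talus[no_talus == 1L] <- 0L
  expect_error(talar_axis(no_talus), "absent")
})

test_that("metatarsal axis finds junctions, falls back on uniform bars", {
  for (md in c(5, 10, 14)) {
    s <- generate_foot(foot_spec(15, md, 22, rng_seed = 40 + md))
    ma <- metatarsal_axis(s$mask)
    expect_lt(abs(declination(ma$axis) - md), 1)
    expect_lt(ma$mt1_proximal_mid[1], ma$mt1_distal_mid[1])
  }
  bar <- rect_mask(label = 2L)
  expect_warning(ma <- metatarsal_axis(bar), "fall")
  expect_lt(abs(declination(ma$axis)), 0.5)
})

test_that("calcaneal inferior tangent is a supporting line at the pitch", {
  for (p in c(10, 22, 30)) {
    s <- generate_foot(foot_spec(15, 9, p, rng_seed = 50 + p))
    ct <- calcaneal_inferior_tangent(s$mask)
    expect_lt(abs(-declination(ct$axis) - p), 0.5)
    # entire bone on or above the line (y-down: on the smaller-y side)
    xy <- footangles:::mask_xy(s$mask == 3L)
    nv <- c(-ct$axis$direction[2], ct$axis$direction[1])
    if (nv[2] < 0) nv <- -nv
    below <- (xy[, 1] - ct$axis$anchor[1]) * nv[1] +
      (xy[, 2] - ct$axis$anchor[2]) * nv[2]
    expect_lt(max(below), 0.6)
  }
  # axis-aligned rectangle: tangent is its bottom edge
  rc <- rect_mask(label = 3L, y0 = 41, y1 = 90, x0 = 31, x1 = 120)
  ct <- calcaneal_inferior_tangent(rc)
  expect_lt(abs(declination(ct$axis)), 1e-6)
  expect_equal(ct$calc_tangent_posterior[2], 90)
  expect_equal(ct$calc_tangent_anterior[2], 90)
  expect_lt(abs(ct$calc_tangent_posterior[1] - 31), 1.5)
  expect_lt(abs(ct$calc_tangent_anterior[1] - 120), 1.5)
})

test_that("weightbearing line joins the two ground contacts", {
  s <- generate_foot(foot_spec(14, 9, 23, rng_seed = 7))
  wb <- weightbearing_line(s$mask)
  expect_false(wb$fallback)
  expect_lt(abs(declination(wb$axis)), 0.2)
  y_g <- max(which(rowSums(s$mask == 3L) > 0))
  expect_equal(wb$wbs_posterior[2], y_g)
  expect_equal(wb$wbs_anterior[2], y_g)

  calc_only <- s$mask
  calc_only[calc_only != 3L] <- 0L
  wb2 <- weightbearing_line(calc_only)
  expect_true(wb2$fallback)
  expect_equal(declination(wb2$axis), 0)

  # deterministic tie-breaks on flat-bottomed rectangles
  m <- matrix(0L, 128, 256)
  m[60:100, 21:80] <- 3L
  m[80:100, 151:230] <- 2L
  wb3 <- weightbearing_line(m)
  expect_equal(wb3$wbs_posterior, c(21, 100))
  expect_equal(wb3$wbs_anterior, c(230, 100))
})

test_that("extract_landmarks recovers generator truth within 3 px", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 1))
  lm <- extract_landmarks(s$mask)
  expect_setequal(names(lm$points), footangles:::LANDMARK_NAMES)
  for (nm in names(lm$points)) {
    err <- sqrt(sum((lm$points[[nm]] - s$landmarks$points[[nm]])^2))
    expect_lt(err, 3)
  }
  expect_true(all(lm$provenance == "automatic"))
  expect_identical(extract_landmarks(s$mask)$points, lm$points)
})

test_that("partial masks give partial landmark sets with named errors", {
  s <- generate_foot(foot_spec(18, 9, 21, rng_seed = 9))
  calc_only <- s$mask
  calc_only[calc_only %in% c(1L, 2L)] <- 0L
  lm <- extract_landmarks(calc_only, partial = TRUE)
  expect_true(all(c("calc_tangent_posterior", "wbs_posterior") %in%
                    names(lm$points)))
  expect_false("talar_body_mid" %in% names(lm$points))
  errs <- attr(lm, "errors")
  expect_true(all(c("talus", "first_metatarsus") %in% names(errs)))
  expect_error(extract_landmarks(calc_only, partial = FALSE), "talus")
})

test_that("landmark overrides replace points and enforce invariants", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 1))
  lm <- extract_landmarks(s$mask)
  expect_identical(apply_overrides(lm, list()), lm)

  shifted <- apply_overrides(lm, list(
    talar_neck_mid = lm$points$talar_neck_mid + c(0, 10)))
  expect_equal(shifted$provenance[["talar_neck_mid"]], "overridden")
  expect_equal(shifted$points$talar_body_mid, lm$points$talar_body_mid)

  m0 <- measure_foot(s$mask)
  m1 <- measure_foot(s$mask, overrides = list(
    talar_neck_mid = lm$points$talar_neck_mid + c(0, 10)))
  expect_gt(abs(m1$meary - m0$meary), 1)
  expect_equal(m1$pitch, m0$pitch)
  expect_equal(m1$landmark_source, "adjusted")

  expect_error(apply_overrides(lm, list(
    talar_neck_mid = lm$points$talar_body_mid - c(5, 0))), "posterior")
  expect_error(apply_overrides(lm, list(talar_neck_mid = c(-3, 10)),
                               bounds = dim(s$mask)), "bounds")
  expect_error(apply_overrides(lm, list(nonexistent_point = c(5, 5))),
               "unknown")
})

test_that("extracted line directions are rotation-equivariant", {
  s <- generate_foot(foot_spec(20, 10, 22, rng_seed = 5))
  base <- footangles:::landmark_lines(extract_landmarks(s$mask))
  for (th in c(-10, -5, 5, 10)) {
    # nearest-neighbour rotation can nick a bone into two fragments; the
    # extractor warns and proceeds on the largest one
    lm <- suppressWarnings(extract_landmarks(rotate_mask(s$mask, th)))
    ln <- footangles:::landmark_lines(lm)
    for (nm in c("talar", "metatarsal", "calc_tangent", "wbs")) {
      dd <- declination(ln[[nm]]) - declination(base[[nm]]) - th
      expect_lt(abs(dd), 0.7)
    }
  }
})

test_that("left-side extraction mirrors the right-side result", {
  r <- generate_foot(foot_spec(17, 9, 24, rng_seed = 13))
  l <- generate_foot(foot_spec(17, 9, 24, rng_seed = 13, side = "left"))
  mr <- measure_foot(r$mask, side = "right")
  ml <- measure_foot(l$mask, side = "left")
  w <- ncol(r$mask)
  for (nm in names(mr$landmarks$points)) {
    mirrored <- c(mirror_x(ml$landmarks$points[[nm]][1], w),
                  ml$landmarks$points[[nm]][2])
    expect_lt(sqrt(sum((mirrored - mr$landmarks$points[[nm]])^2)), 1)
  }
  expect_equal(ml$meary, mr$meary, tolerance = 1e-8)
  expect_equal(ml$pitch, mr$pitch, tolerance = 1e-8)
})
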