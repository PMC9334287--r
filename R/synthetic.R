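#' Specification for a synthetic foot silhouette
#'
#' Describes one synthetic lateral "radiograph": stylized silhouettes of the
#' talus, first metatarsus and calcaneus on a flat ground line, with known
#' bone-axis declinations. Declinations are plantar tilts: positive values
#' tilt the axis below the horizontal, toward the ground, going anteriorly
#' (toes point toward +x, y increases downward). By construction the
#' ground-truth Meary angle is
#' \code{metatarsal_declination - talar_declination} and the ground-truth
#' calcaneal pitch is \code{calcaneal_pitch}.
#'
#' @param talar_declination Plantar tilt of the talar axis, degrees.
#' @param metatarsal_declination Plantar tilt of the first-metatarsal axis,
#'   degrees.
#' @param calcaneal_pitch Angle of the inferior calcaneal border above the
#'   ground line, degrees, in [0, 60).
#' @param image_size Canvas size as c(height, width) pixels, each >= 256.
#' @param scale Pixels per foot-length unit; bone dimensions scale with it.
#' @param side "right" (canonical, toes toward +x) or "left" (mirrored).
#' @param boundary_noise_sd Standard deviation (pixels) of Gaussian jitter
#'   applied to silhouette polygon vertices. The default 0 keeps the masks
#'   exact so ground-truth angles are realized up to rasterization only.
#' @param rng_seed Integer seed; the sample is bit-reproducible given it.
#' @return An object of class \code{foot_spec}.
#' @export
foot_spec <- function(talar_declination, metatarsal_declination,
                      calcaneal_pitch, image_size = c(384L, 512L),
                      scale = 40, side = c("right", "left"),
                      boundary_noise_sd = 0, rng_seed = 1L) {
  side <- match.arg(side)
  stopifnot(length(image_size) == 2, all(image_size >= 256),
            scale > 0, calcaneal_pitch >= 0, calcaneal_pitch < 60,
            abs(talar_declination) < 60, abs(metatarsal_declination) < 60,
            boundary_noise_sd >= 0)
  structure(list(talar_declination = talar_declination,
                 metatarsal_declination = metatarsal_declination,
                 calcaneal_pitch = calcaneal_pitch,
                 image_size = as.integer(image_size), scale = scale,
                 side = side, boundary_noise_sd = boundary_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "foot_spec")
}

# Even-odd scanline polygon rasterization onto an h x w pixel grid.
# poly: 2-column matrix of (x, y) vertices; pixels are tested at their
# integer centres.
#' @keywords internal
rasterize_polygon <- function(poly, h, w) {
  xmin <- max(1L, floor(min(poly[, 1])))
  xmax <- min(w, ceiling(max(poly[, 1])))
  ymin <- max(1L, floor(min(poly[, 2])))
  ymax <- min(h, ceiling(max(poly[, 2])))
  out <- matrix(FALSE, h, w)
  if (xmin > xmax || ymin > ymax) return(out)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  out[cbind(py[inside], px[inside])] <- TRUE
  out
}

# Replace each polygon vertex by two points a fraction `cut` along the two
# adjacent edges (chamfered corners; edge directions are preserved).
#' @keywords internal
chamfer_polygon <- function(poly, cut = 0.12) {
  nv <- nrow(poly)
  out <- NULL
  for (i in seq_len(nv)) {
    prev <- poly[if (i == 1) nv else i - 1, ]
    cur <- poly[i, ]
    nxt <- poly[if (i == nv) 1 else i + 1, ]
    out <- rbind(out, cur + cut * (prev - cur), cur + cut * (nxt - cur))
  }
  out
}

# Tapered-tube polygon around centreline C(f) = origin + f*len*dir with
# half-width halfw(f); f sampled on a fine grid.
#' @keywords internal
tube_polygon <- function(origin, dir_deg, len, halfw_fun, round_frac = 0) {
  th <- dir_deg * pi / 180
  d <- c(cos(th), sin(th))
  nv <- c(-sin(th), cos(th))   # +y side ("caudad", toward the ground)
  fs <- seq(0, 1, by = 0.02)
  w <- vapply(fs, halfw_fun, numeric(1))
  if (round_frac > 0) {
    w <- w * sqrt(pmin(1, fs / round_frac)) * sqrt(pmin(1, (1 - fs) / round_frac))
  }
  centre <- cbind(origin[1] + fs * len * d[1], origin[2] + fs * len * d[2])
  up <- centre - outer(w, nv)
  dn <- centre + outer(w, nv)
  rbind(up, dn[rev(seq_len(nrow(dn))), ])
}

#' Generate one synthetic foot sample
#'
#' Builds the three bone silhouettes as parametric polygons, rasterizes them
#' into a label mask, renders a noisy grayscale image, and records the
#' ground-truth landmarks and angles implied by the construction. The lowest
#' pixels of the calcaneus and the first metatarsus are placed exactly on a
#' horizontal ground line, so the weightbearing surface is horizontal and the
#' ground-truth calcaneal pitch is realized exactly.
#'
#' Silhouette structure: the calcaneus is a chamfered quadrilateral whose
#' inferior edge rises anteriorly at the requested pitch; the talus is a
#' tapered capsule whose posterior (body) width is 1.7x its anterior (neck)
#' width; the first metatarsus is a narrow shaft with metaphyseal flares 1.5x
#' the diaphyseal width at both ends.
#'
#' @param spec A \code{\link{foot_spec}}.
#' @return An object of class \code{foot_sample}: list with \code{image}
#'   (numeric matrix, 0-255), \code{mask} (integer label matrix),
#'   \code{landmarks} (ground-truth \code{\link{foot_landmarks}}),
#'   \code{truth_meary}, \code{truth_pitch}, \code{pp_by_meary},
#'   \code{pp_by_pitch}, \code{side}, and \code{spec}.
#' @export
generate_foot <- function(spec) {
  stopifnot(inherits(spec, "foot_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  u <- spec$scale
  y_g <- round(0.92 * h)
  t_deg <- spec$talar_declination
  m_deg <- spec$metatarsal_declination
  p_deg <- spec$calcaneal_pitch
  p <- p_deg * pi / 180

  with_seed(spec$rng_seed, {
    jitter_poly <- function(poly) {
      if (spec$boundary_noise_sd <= 0) return(poly)
      poly + matrix(stats::rnorm(length(poly), 0, spec$boundary_noise_sd),
                    nrow(poly), 2)
    }

    ## --- calcaneus: chamfered quadrilateral, inferior edge at angle p ---
    Lc <- 3.5 * u; hc <- 1.5 * u
    P0 <- c(1.5 * u, y_g)
    P1 <- P0 + Lc * c(cos(p), -sin(p))
    P2 <- P1 + c(-0.3 * u, -0.8 * hc)
    P3 <- P0 + c(0.3 * u, -hc)
    calc_quad <- rbind(P0, P1, P2, P3)
    calc_poly <- jitter_poly(chamfer_polygon(calc_quad, 0.07))

    ## --- talus: tapered capsule along declination t ---
    Lt <- 2.8 * u; hb <- 0.85 * u; hn <- 0.5 * u
    TP <- c(0.30 * w, 0.38 * h)
    talus_halfw <- function(f) {
      if (f <= 0.45) hb
      else if (f >= 0.85) hn
      else hb + (hn - hb) * (f - 0.45) / 0.40
    }
    talus_poly <- jitter_poly(tube_polygon(TP, t_deg, Lt, talus_halfw,
                                           round_frac = 0.06))

    ## --- first metatarsus: flared shaft along declination m ---
    Lm <- 4.2 * u; hd <- 0.30 * u; hm <- 0.45 * u
    M0 <- c(0.58 * w, 0.70 * h)
    mt_halfw <- function(f) {
      if (f < 0.15) hm + (hd - hm) * f / 0.15
      else if (f > 0.85) hd + (hm - hd) * (f - 0.85) / 0.15
      else hd
    }
    mt_poly <- jitter_poly(tube_polygon(M0, m_deg, Lm, mt_halfw))

    # drop the ground-contact bones onto the ground line: analytic shift of
    # the polygon first (so nothing is clipped while still off the ground),
    # then a <=1 px integer correction after rasterization
    calc_dy0 <- y_g - max(calc_poly[, 2])
    calc_poly[, 2] <- calc_poly[, 2] + calc_dy0
    mt_dy0 <- y_g - max(mt_poly[, 2])
    mt_poly[, 2] <- mt_poly[, 2] + mt_dy0

    polys <- list(talus = talus_poly, first_metatarsus = mt_poly,
                  calcaneus = calc_poly)
    for (nm in names(polys)) {
      pl <- polys[[nm]]
      if (any(pl[, 1] < 2) || any(pl[, 1] > w - 1) || any(pl[, 2] < 2) ||
          any(pl[, 2] > h - 1)) {
        stop(sprintf("%s silhouette leaves the canvas; enlarge image_size or reduce declinations", nm))
      }
    }

    # scanline fill can leave an isolated pixel at acute polygon corners;
    # keep each bone's largest 4-connected component
    calc_m <- largest_component4(rasterize_polygon(calc_poly, h, w))
    talus_m <- largest_component4(rasterize_polygon(talus_poly, h, w))
    mt_m <- largest_component4(rasterize_polygon(mt_poly, h, w))

    shift_to_ground <- function(m) {
      ys <- which(rowSums(m) > 0)
      dy <- y_g - max(ys)
      list(mask = translate_mask(m * 1L, 0L, as.integer(dy)) > 0, dy = dy)
    }
    sc <- shift_to_ground(calc_m); calc_m <- sc$mask
    sm <- shift_to_ground(mt_m); mt_m <- sm$mask

    if (any(calc_m & talus_m) || any(calc_m & mt_m) || any(talus_m & mt_m)) {
      stop("bone silhouettes overlap for this specification")
    }
    sizes <- c(talus = sum(talus_m), first_metatarsus = sum(mt_m),
               calcaneus = sum(calc_m))
    if (any(sizes < 500)) {
      stop("bone silhouette smaller than 500 pixels: ",
           paste(names(sizes)[sizes < 500], collapse = ", "))
    }

    mask <- matrix(0L, h, w)
    mask[talus_m] <- BONE_LABELS[["talus"]]
    mask[mt_m] <- BONE_LABELS[["first_metatarsus"]]
    mask[calc_m] <- BONE_LABELS[["calcaneus"]]

    ## --- ground-truth landmarks ---
    tdir <- c(cos(t_deg * pi / 180), sin(t_deg * pi / 180))
    mdir <- c(cos(m_deg * pi / 180), sin(m_deg * pi / 180))
    cm_shift <- c(0, mt_dy0 + sm$dy)
    # metaphyseal-diaphyseal junction: where the linear flare ramp crosses
    # 1.2 x the diaphyseal width
    f_j <- 0.15 * (hm / hd - 1.2) / (hm / hd - 1)
    calc_shift <- c(0, calc_dy0 + sc$dy)
    cut <- 0.07
    pts <- list(
      talar_body_mid = TP + 0.35 * Lt * tdir,
      talar_neck_mid = TP + 0.78 * Lt * tdir,
      mt1_proximal_mid = M0 + f_j * Lm * mdir + cm_shift,
      mt1_distal_mid = M0 + (1 - f_j) * Lm * mdir + cm_shift,
      calc_tangent_posterior = P0 + cut * (P1 - P0) + calc_shift,
      calc_tangent_anterior = P1 - cut * (P1 - P0) + calc_shift
    )
    # weightbearing contacts: lowest pixels of calcaneus / first metatarsus
    cxy <- mask_xy(calc_m)
    clow <- cxy[cxy[, 2] == max(cxy[, 2]), , drop = FALSE]
    mxy <- mask_xy(mt_m)
    mlow <- mxy[mxy[, 2] == max(mxy[, 2]), , drop = FALSE]
    pts$wbs_posterior <- c(min(clow[, 1]), max(cxy[, 2]))
    pts$wbs_anterior <- c(max(mlow[, 1]), max(mxy[, 2]))

    ## --- image channel ---
    img <- matrix(20, h, w)
    img[talus_m] <- 190
    img[mt_m] <- 170
    img[calc_m] <- 210
    img <- img + matrix(stats::rnorm(h * w, 0, 8), h, w)
    img <- pmin(pmax(img, 0), 255)

    if (spec$side == "left") {
      img <- mirror_raster(img)
      mask <- mirror_raster(mask)
      pts <- lapply(pts, function(pp) c(mirror_x(pp[1], w), pp[2]))
      # mirroring reverses anterior/posterior x ordering; keep names true
      # to anatomy (posterior = heel side), coordinates in the left frame
    }

    truth_meary <- m_deg - t_deg
    cls <- classify_pp(truth_meary, p_deg)
    structure(list(
      image = img, mask = mask,
      landmarks = foot_landmarks(pts, provenance = "automatic"),
      truth_meary = truth_meary, truth_pitch = p_deg,
      pp_by_meary = cls$pp_by_meary, pp_by_pitch = cls$pp_by_pitch,
      side = spec$side, spec = spec), class = "foot_sample")
  })
}

#' @export
print.foot_sample <- function(x, ...) {
  cat(sprintf("<foot_sample> %dx%d %s foot: Meary %.1f deg, pitch %.1f deg (%s/%s)\n",
              nrow(x$mask), ncol(x$mask), x$side, x$truth_meary,
              x$truth_pitch,
              if (x$pp_by_meary) "PP-by-Meary" else "non-PP-by-Meary",
              if (x$pp_by_pitch) "PP-by-pitch" else "non-PP-by-pitch"))
  invisible(x)
}

#' Generate a cohort of synthetic feet with a fixed flatfoot prevalence
#'
#' Draws \code{round(n * pp_fraction)} samples from a pes-planus stratum
#' (ground-truth Meary angle uniform in [-25, -5), calcaneal pitch in
#' [8, 16]) and the rest from a non-PP stratum (Meary in [-3, 12], pitch in
#' [20, 32]); metatarsal declination is uniform in [6, 14] and the talar
#' declination is set to realize the drawn Meary angle. The stratum ranges
#' bracket the clinical cutoffs with margin so truth labels are unambiguous.
#'
#' @param n Number of samples (>= 1).
#' @param pp_fraction Fraction of samples that are PP by the Meary criterion.
#' @param rng_seed Integer seed; the cohort is reproducible given it.
#' @param image_size,scale Passed to \code{\link{foot_spec}}.
#' @return List of \code{foot_sample} objects; each has an \code{$id}.
#' @export
make_cohort <- function(n, pp_fraction, rng_seed = 1L,
                        image_size = c(384L, 512L), scale = 40) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(pp_fraction >= 0, pp_fraction <= 1)
  n_pp <- round(n * pp_fraction)
  with_seed(rng_seed, {
    is_pp <- c(rep(TRUE, n_pp), rep(FALSE, n - n_pp))
    meary <- ifelse(is_pp, stats::runif(n, -25, -5),
                    stats::runif(n, -3, 12))
    pitch <- ifelse(is_pp, stats::runif(n, 8, 16), stats::runif(n, 20, 32))
    met <- stats::runif(n, 6, 14)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sp <- foot_spec(talar_declination = met[i] - meary[i],
                      metatarsal_declination = met[i],
                      calcaneal_pitch = pitch[i],
                      image_size = image_size, scale = scale,
                      rng_seed = seeds[i])
      smp <- generate_foot(sp)
      smp$id <- sprintf("S%03d", i)
      smp
    })
  })
}

#' Degrade a label mask to a target Dice similarity
#'
#' Emulates imperfect segmentation: each bone's boundary is randomly eroded
#' and dilated (balanced numbers of removed and added boundary pixels) until
#' the per-bone Dice coefficient against the input reaches
#' \code{target_dice} within 0.02. Bone connectivity is preserved; the
#' perturbation is re-drawn if a draw fragments a bone.
#'
#' @param mask Integer label mask.
#' @param target_dice Target per-bone Dice, in (0.5, 1].
#' @param rng_seed Integer seed.
#' @return Degraded label mask.
#' @export
degrade_mask <- function(mask, target_dice, rng_seed = 1L) {
  if (!(target_dice > 0.5 && target_dice <= 1)) {
    stop("target_dice must be in (0.5, 1]")
  }
  validate_mask(mask)
  if (target_dice == 1) return(mask)
  with_seed(rng_seed, {
    out <- mask
    for (lab in setdiff(sort(unique(as.vector(mask))), 0L)) {
      orig <- mask == lab
      A <- sum(orig)
      # pixels this bone may grow into: background of the full mask plus
      # its own original footprint (never another bone)
      allowed <- mask == 0L | orig
      batch <- max(20L, round(0.01 * A))
      done <- FALSE
      for (attempt in seq_len(10)) {
        work <- orig
        for (round_i in seq_len(400)) {
          d <- 2 * sum(orig & work) / (A + sum(work))
          if (d <= target_dice) break
          bd <- boundary4(work)
          rem <- which(bd$inner)
          rem <- rem[sample.int(length(rem), min(batch, length(rem)))]
          add <- which(bd$outer & allowed)
          add <- add[sample.int(length(add), min(batch, length(add)))]
          work[rem] <- FALSE
          work[add] <- TRUE
        }
        if (n_components4(work) > 1) work <- largest_component4(work)
        d <- 2 * sum(orig & work) / (A + sum(work))
        if (abs(d - target_dice) <= 0.02 && sum(work) > 0) {
          out[orig & !work] <- 0L
          out[work & !orig] <- lab
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop(sprintf("could not reach Dice %.2f for label %d while keeping the bone connected",
                     target_dice, lab))
      }
    }
    out
  })
}
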