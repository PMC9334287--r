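#' Construct a 2-D line from anchor and direction
#'
#' Lines use the raster coordinate convention shared by the whole package:
#' x increases rightward, y increases downward, and under canonical (right
#' foot, toes toward +x) orientation every axis direction has dx > 0.
#'
#' @param anchor Numeric c(x, y).
#' @param direction Numeric c(dx, dy); normalised, sign-fixed to dx > 0
#'   (for vertical lines, dy > 0).
#' @return Object of class \code{foot_line}.
#' @export
foot_line <- function(anchor, direction) {
  stopifnot(length(anchor) == 2, length(direction) == 2,
            all(is.finite(anchor)), all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("degenerate line direction")
  d <- direction / nrm
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  structure(list(anchor = as.numeric(anchor), direction = as.numeric(d)),
            class = "foot_line")
}

#' Line through two points
#' @param a,b Numeric c(x, y) points; must be distinct.
#' @return \code{\link{foot_line}} through both.
#' @export
line_through <- function(a, b) foot_line(a, c(b[1] - a[1], b[2] - a[2]))

#' @export
print.foot_line <- function(x, ...) {
  cat(sprintf("<foot_line> anchor (%.1f, %.1f), direction (%.4f, %.4f), declination %.2f deg\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2],
              declination(x)))
  invisible(x)
}

LANDMARK_NAMES <- c("talar_body_mid", "talar_neck_mid", "mt1_proximal_mid",
                    "mt1_distal_mid", "calc_tangent_posterior",
                    "calc_tangent_anterior", "wbs_posterior", "wbs_anterior")

#' Landmark set defining both clinical angles
#'
#' Eight named construction points: chord midpoints through the talar body
#' and neck (talar axis), chord midpoints at the proximal and distal
#' metaphyseal-diaphyseal junctions of the first metatarsus (metatarsal
#' axis), the two contact points of the inferior calcaneal tangent, and the
#' two ground contacts of the weightbearing surface. Under canonical
#' orientation each pair is ordered posterior-to-anterior in x.
#'
#' @param points Named list of numeric c(x, y); any subset of the eight
#'   canonical names.
#' @param provenance Either a single value recycled to all points or a named
#'   character vector over the same names; each entry one of "automatic",
#'   "overridden", "manual".
#' @return Object of class \code{foot_landmarks}.
#' @export
foot_landmarks <- function(points, provenance = "automatic") {
  stopifnot(is.list(points))
  unknown <- setdiff(names(points), LANDMARK_NAMES)
  if (length(unknown) > 0) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  }
  points <- lapply(points, function(p) {
    stopifnot(length(p) == 2, all(is.finite(p)))
    as.numeric(p)
  })
  if (length(provenance) == 1) {
    provenance <- stats::setNames(rep(provenance, length(points)),
                                  names(points))
  }
  stopifnot(all(provenance %in% c("automatic", "overridden", "manual")))
  structure(list(points = points,
                 provenance = provenance[names(points)]),
            class = "foot_landmarks")
}

#' @export
print.foot_landmarks <- function(x, ...) {
  cat(sprintf("<foot_landmarks> %d of %d points\n", length(x$points),
              length(LANDMARK_NAMES)))
  for (nm in intersect(LANDMARK_NAMES, names(x$points))) {
    p <- x$points[[nm]]
    cat(sprintf("  %-24s (%7.2f, %7.2f)  [%s]\n", nm, p[1], p[2],
                x$provenance[[nm]]))
  }
  invisible(x)
}

# Pull pixel coordinates of a label, reduced to its largest 4-connected
# component; errors when absent or too small.
#' @keywords internal
label_pixels <- function(mask, label, min_pixels = 50) {
  m <- mask == label
  if (!any(m)) stop(sprintf("label %s (%s) absent from mask", label,
                            label_name(label)))
  if (n_components4(m) > 1) m <- largest_component4(m)
  if (sum(m) < min_pixels) {
    stop(sprintf("label %s (%s) has fewer than %d pixels", label,
                 label_name(label), min_pixels))
  }
  m
}

#' Principal axis of a bone mask
#'
#' Anchor is the pixel centroid; direction is the dominant eigenvector of
#' the pixel-coordinate covariance, sign-fixed to dx > 0. Isotropic shapes
#' (tied eigenvalues) resolve to the +x direction.
#'
#' @param mask Integer label mask.
#' @param label Bone label (see \code{\link{BONE_LABELS}}).
#' @return \code{\link{foot_line}}.
#' @export
principal_axis <- function(mask, label) {
  m <- label_pixels(mask, label)
  xy <- mask_xy(m)
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-9 * max(eg$values[1], 1)) {
    d <- c(1, 0)  # isotropic: tie broken toward +x
  } else {
    d <- eg$vectors[, 1]
  }
  foot_line(ctr, d)
}

#' Width profile of a bone along an axis
#'
#' At each station (equally spaced fractions of the projected extent of the
#' bone along the axis, clipped to [0.05, 0.95]) the chord is the set of
#' bone pixels within a thin band perpendicular to the axis; the width is
#' the distance between the two extreme pixels along the perpendicular and
#' the midpoint is their mean. Stations whose band contains no bone pixel
#' are flagged empty.
#'
#' @param mask Integer label mask.
#' @param label Bone label.
#' @param axis \code{\link{foot_line}}, typically from
#'   \code{\link{principal_axis}}.
#' @param n_stations Number of stations (>= 11).
#' @return Data frame of class \code{width_profile} with columns
#'   \code{station}, \code{width}, \code{mid_x}, \code{mid_y}, \code{empty}.
#' @export
width_profile <- function(mask, label, axis, n_stations = 101) {
  stopifnot(inherits(axis, "foot_line"), n_stations >= 11)
  m <- label_pixels(mask, label)
  xy <- mask_xy(m)
  d <- axis$direction
  nvec <- c(-d[2], d[1])
  t_all <- (xy[, 1] - axis$anchor[1]) * d[1] + (xy[, 2] - axis$anchor[2]) * d[2]
  u_all <- (xy[, 1] - axis$anchor[1]) * nvec[1] + (xy[, 2] - axis$anchor[2]) * nvec[2]
  tmin <- min(t_all); tmax <- max(t_all)
  if (tmax - tmin < 1e-9) stop("degenerate axis projection")
  stations <- seq(0.05, 0.95, length.out = n_stations)
  # band width scales with the bone so results are scale-invariant
  half_band <- max(0.6, 0.0045 * (tmax - tmin))
  out <- data.frame(station = stations, width = NA_real_,
                    mid_x = NA_real_, mid_y = NA_real_, empty = TRUE)
  for (i in seq_along(stations)) {
    s <- tmin + stations[i] * (tmax - tmin)
    sel <- abs(t_all - s) <= half_band
    if (!any(sel)) next
    us <- u_all[sel]
    i_lo <- which.min(us); i_hi <- which.max(us)
    p_lo <- xy[sel, , drop = FALSE][i_lo, ]
    p_hi <- xy[sel, , drop = FALSE][i_hi, ]
    out$width[i] <- us[i_hi] - us[i_lo]
    out$mid_x[i] <- (p_lo[1] + p_hi[1]) / 2
    out$mid_y[i] <- (p_lo[2] + p_hi[2]) / 2
    out$empty[i] <- FALSE
  }
  class(out) <- c("width_profile", "data.frame")
  out
}

# Chord midpoint at an arbitrary extent fraction, searching +/- search_frac
# around the requested fraction if the exact band is empty.
#' @keywords internal
chord_at_fraction <- function(mask, label, axis, frac, search_frac = 0.05) {
  m <- label_pixels(mask, label)
  xy <- mask_xy(m)
  d <- axis$direction
  nvec <- c(-d[2], d[1])
  t_all <- (xy[, 1] - axis$anchor[1]) * d[1] + (xy[, 2] - axis$anchor[2]) * d[2]
  u_all <- (xy[, 1] - axis$anchor[1]) * nvec[1] + (xy[, 2] - axis$anchor[2]) * nvec[2]
  tmin <- min(t_all); tmax <- max(t_all)
  ext <- tmax - tmin
  band <- max(0.8, 0.018 * ext)   # relative to bone: scale-invariant
  for (f in unique(pmin(1, pmax(0, frac + c(0, seq(-1, 1, by = 0.2) * search_frac))))) {
    s <- tmin + f * ext
    sel <- abs(t_all - s) <= band
    if (any(sel)) {
      # average the k most extreme boundary pixels on each margin (about
      # one per pixel column in the band): damps single-pixel jitter
      us <- u_all[sel]
      sub <- xy[sel, , drop = FALSE]
      k <- min(length(us), max(1L, round(2 * band)))
      ord <- order(us)
      lo <- ord[seq_len(k)]; hi <- rev(ord)[seq_len(k)]
      p_lo <- colMeans(sub[lo, , drop = FALSE])
      p_hi <- colMeans(sub[hi, , drop = FALSE])
      return(list(mid = (p_lo + p_hi) / 2,
                  width = mean(us[hi]) - mean(us[lo])))
    }
  }
  stop(sprintf("empty chord at station %.2f for label %s", frac,
               label_name(label)))
}

#' Talar axis from body and neck chord midpoints
#'
#' The talar long axis joins the midpoint of a chord through the talar body
#' (the wide posterior portion) and the midpoint of a chord through the
#' talar neck (the narrow anterior portion), each chord taken perpendicular
#' to the principal axis at a fixed fraction of the bone's extent.
#'
#' @param mask Integer label mask.
#' @param body_station,neck_station Extent fractions for the two chords.
#' @return List with \code{axis} (\code{foot_line}), \code{talar_body_mid},
#'   \code{talar_neck_mid}.
#' @export
talar_axis <- function(mask, body_station = 0.35, neck_station = 0.78) {
  lab <- BONE_LABELS[["talus"]]
  pax <- principal_axis(mask, lab)
  body <- chord_at_fraction(mask, lab, pax, body_station)
  neck <- chord_at_fraction(mask, lab, pax, neck_station)
  list(axis = line_through(body$mid, neck$mid),
       talar_body_mid = body$mid, talar_neck_mid = neck$mid)
}

#' First-metatarsal axis from metaphyseal-diaphyseal junction midpoints
#'
#' From a 101-station width profile, the diaphyseal width is the minimum
#' over stations in [0.30, 0.70]. Walking outward from 0.30 toward the
#' proximal end, the proximal junction is the first station whose width
#' strictly exceeds \code{junction_ratio} times that minimum; the distal
#' junction is found symmetrically from 0.70 toward the distal end. The
#' axis joins the chord midpoints at the two junction stations. A bone
#' without detectable flares falls back to stations 0.15 and 0.85 with a
#' warning.
#'
#' @param mask Integer label mask.
#' @param junction_ratio Width multiplier defining the junction (default 1.20).
#' @param n_stations Stations in the width profile.
#' @return List with \code{axis}, \code{mt1_proximal_mid},
#'   \code{mt1_distal_mid}.
#' @export
metatarsal_axis <- function(mask, junction_ratio = 1.20, n_stations = 101) {
  lab <- BONE_LABELS[["first_metatarsus"]]
  pax <- principal_axis(mask, lab)
  wp <- width_profile(mask, lab, pax, n_stations)
  mid_zone <- !wp$empty & wp$station >= 0.30 & wp$station <= 0.70
  if (!any(mid_zone)) stop("no usable mid-shaft stations on first metatarsus")
  w_min <- min(wp$width[mid_zone])
  thresh <- junction_ratio * w_min

  prox_cand <- which(!wp$empty & wp$station <= 0.30)
  prox_cand <- prox_cand[order(wp$station[prox_cand], decreasing = TRUE)]
  prox_i <- NA_integer_
  for (i in prox_cand) if (wp$width[i] > thresh) { prox_i <- i; break }

  dist_cand <- which(!wp$empty & wp$station >= 0.70)
  dist_cand <- dist_cand[order(wp$station[dist_cand])]
  dist_i <- NA_integer_
  for (i in dist_cand) if (wp$width[i] > thresh) { dist_i <- i; break }

  if (is.na(prox_i) || is.na(dist_i)) {
    warning("no metaphyseal flare detected; falling back to stations 0.15 and 0.85")
    prox <- chord_at_fraction(mask, lab, pax, 0.15)
    dist <- chord_at_fraction(mask, lab, pax, 0.85)
    pmid <- prox$mid; dmid <- dist$mid
  } else {
    pmid <- c(wp$mid_x[prox_i], wp$mid_y[prox_i])
    dmid <- c(wp$mid_x[dist_i], wp$mid_y[dist_i])
  }
  list(axis = line_through(pmid, dmid),
       mt1_proximal_mid = pmid, mt1_distal_mid = dmid)
}

#' Inferior tangent line of the calcaneus
#'
#' Computes the convex hull of the calcaneal outline pixels, selects among
#' the lower hull edges (outward normal pointing downward, toward +y) the
#' edge with the greatest horizontal span, and returns it as the line
#' outlining the inferior calcaneal border. By the hull property the whole
#' bone lies on or above this line (within rasterization tolerance).
#'
#' @param mask Integer label mask.
#' @return List with \code{axis} (the tangent \code{foot_line}),
#'   \code{calc_tangent_posterior}, \code{calc_tangent_anterior}.
#' @export
calcaneal_inferior_tangent <- function(mask) {
  lab <- BONE_LABELS[["calcaneus"]]
  m <- label_pixels(mask, lab)
  xy <- mask_xy(outline8(m))
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(hull) < 3) stop("degenerate calcaneus hull (collinear mask)")
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  ctr <- c(mean(hx), mean(hy))
  nh <- length(hull)
  best_span <- -1; best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1 else i + 1
    e <- c(hx[j] - hx[i], hy[j] - hy[i])
    nrm <- c(-e[2], e[1])
    mid <- c((hx[i] + hx[j]) / 2, (hy[i] + hy[j]) / 2)
    if (sum(nrm * (mid - ctr)) < 0) nrm <- -nrm   # outward
    if (nrm[2] > 0) {                             # lower edge (faces ground)
      span <- abs(e[1])
      if (span > best_span) {
        best_span <- span
        best <- list(a = c(hx[i], hy[i]), b = c(hx[j], hy[j]))
      }
    }
  }
  if (is.null(best)) stop("no inferior hull edge found for calcaneus")
  # rasterization splits a straight border into near-collinear hull edges;
  # gather every hull vertex near the winning edge's line and refit the
  # tangent through them (orthogonal regression), which averages out the
  # half-pixel staircase of the outline
  ev <- best$b - best$a
  ev <- ev / sqrt(sum(ev^2))
  tol <- max(0.75, 0.0075 * (max(hx) - min(hx)))
  dist <- abs((hx - best$a[1]) * ev[2] - (hy - best$a[2]) * ev[1])
  on_line <- dist <= tol
  xs_on <- hx[on_line]; ys_on <- hy[on_line]
  if (sum(on_line) >= 3) {
    cv <- stats::cov(cbind(xs_on, ys_on))
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    if (ev[1] < 0) ev <- -ev
  }
  # supporting-line shift: slide the fitted line plantarward so the whole
  # hull stays on or above it
  nvec <- c(-ev[2], ev[1])           # points toward +y (downward)
  if (nvec[2] < 0) nvec <- -nvec
  anchor <- c(mean(xs_on), mean(ys_on))
  resid <- (hx - anchor[1]) * nvec[1] + (hy - anchor[2]) * nvec[2]
  anchor <- anchor + max(resid) * nvec
  # tangent contacts: extreme hull vertices lying on the supporting line
  res_all <- -((hx - anchor[1]) * nvec[1] + (hy - anchor[2]) * nvec[2])
  keep <- res_all <= tol
  xs_k <- hx[keep]; ys_k <- hy[keep]
  proj <- (xs_k - anchor[1]) * ev[1] + (ys_k - anchor[2]) * ev[2]
  snap <- function(t) anchor + t * ev
  pts <- list(post = snap(min(proj)), ant = snap(max(proj)))
  list(axis = line_through(pts$post, pts$ant),
       calc_tangent_posterior = pts$post,
       calc_tangent_anterior = pts$ant)
}

#' Weightbearing surface line
#'
#' The ground line of the standing foot: through the lowest pixel of the
#' calcaneus (ties broken toward smaller x) and the lowest pixel of the
#' first metatarsus (ties broken toward larger x). When the metatarsus is
#' absent a horizontal line through the calcaneal contact is used.
#'
#' @param mask Integer label mask.
#' @return List with \code{axis}, \code{wbs_posterior}, \code{wbs_anterior},
#'   and \code{fallback} (TRUE when the horizontal fallback was used).
#' @export
weightbearing_line <- function(mask) {
  calc <- label_pixels(mask, BONE_LABELS[["calcaneus"]])
  cxy <- mask_xy(calc)
  cy <- max(cxy[, 2])
  cx <- min(cxy[cxy[, 2] == cy, 1])
  post <- c(cx, cy)
  has_mt <- any(mask == BONE_LABELS[["first_metatarsus"]])
  if (!has_mt) {
    return(list(axis = foot_line(post, c(1, 0)), wbs_posterior = post,
                wbs_anterior = post + c(1, 0), fallback = TRUE))
  }
  mt <- label_pixels(mask, BONE_LABELS[["first_metatarsus"]])
  mxy <- mask_xy(mt)
  my <- max(mxy[, 2])
  mx <- max(mxy[mxy[, 2] == my, 1])
  ant <- c(mx, my)
  list(axis = line_through(post, ant), wbs_posterior = post,
       wbs_anterior = ant, fallback = FALSE)
}

#' Extract the full landmark set from bone masks
#'
#' Composes \code{\link{talar_axis}}, \code{\link{metatarsal_axis}},
#' \code{\link{calcaneal_inferior_tangent}} and
#' \code{\link{weightbearing_line}}. Assumes canonical orientation (toes
#' toward +x); mirror left-foot masks first (see
#' \code{\link{mirror_raster}}). When a bone is missing its points are
#' omitted and the errors collected in the \code{errors} attribute (or
#' raised if \code{partial = FALSE}).
#'
#' @param mask Integer label mask.
#' @param partial Return a partial set (with an \code{errors} attribute)
#'   instead of failing when a bone's landmarks cannot be derived.
#' @param body_station,neck_station,junction_ratio Tuning parameters passed
#'   through to the per-bone operations.
#' @return \code{\link{foot_landmarks}} with provenance "automatic".
#' @export
extract_landmarks <- function(mask, partial = FALSE, body_station = 0.35,
                              neck_station = 0.78, junction_ratio = 1.20) {
  validate_mask(mask)
  pts <- list()
  errs <- character(0)
  grab <- function(expr, bone) {
    tryCatch(expr, error = function(e) {
      if (!partial) stop(sprintf("%s: %s", bone, conditionMessage(e)),
                         call. = FALSE)
      errs[[bone]] <<- conditionMessage(e)
      NULL
    })
  }
  ta <- grab(talar_axis(mask, body_station, neck_station), "talus")
  if (!is.null(ta)) {
    pts$talar_body_mid <- ta$talar_body_mid
    pts$talar_neck_mid <- ta$talar_neck_mid
  }
  ma <- grab(metatarsal_axis(mask, junction_ratio), "first_metatarsus")
  if (!is.null(ma)) {
    pts$mt1_proximal_mid <- ma$mt1_proximal_mid
    pts$mt1_distal_mid <- ma$mt1_distal_mid
  }
  ct <- grab(calcaneal_inferior_tangent(mask), "calcaneus")
  if (!is.null(ct)) {
    pts$calc_tangent_posterior <- ct$calc_tangent_posterior
    pts$calc_tangent_anterior <- ct$calc_tangent_anterior
  }
  wb <- grab(weightbearing_line(mask), "weightbearing_surface")
  if (!is.null(wb)) {
    pts$wbs_posterior <- wb$wbs_posterior
    pts$wbs_anterior <- wb$wbs_anterior
  }
  lm <- foot_landmarks(pts, provenance = "automatic")
  attr(lm, "errors") <- errs
  lm
}

# Ordering invariants under canonical orientation.
#' @keywords internal
check_landmark_order <- function(lm) {
  p <- lm$points
  chk <- function(a, b) {
    if (!is.null(p[[a]]) && !is.null(p[[b]]) && p[[a]][1] >= p[[b]][1]) {
      stop(sprintf("landmark ordering violated: %s must lie posterior to (left of) %s",
                   a, b))
    }
  }
  chk("talar_body_mid", "talar_neck_mid")
  chk("mt1_proximal_mid", "mt1_distal_mid")
  chk("calc_tangent_posterior", "calc_tangent_anterior")
  invisible(lm)
}

#' Override automatically suggested landmarks
#'
#' Replaces any subset of the extracted points with measurer-supplied
#' coordinates (the programmatic counterpart of interactive landmark
#' adjustment); provenance of replaced points becomes "overridden".
#'
#' @param landmarks \code{\link{foot_landmarks}}.
#' @param overrides Named list of c(x, y) replacement points.
#' @param bounds Optional c(height, width) raster bounds the overrides must
#'   fall inside.
#' @return Updated \code{foot_landmarks}.
#' @export
apply_overrides <- function(landmarks, overrides, bounds = NULL) {
  stopifnot(inherits(landmarks, "foot_landmarks"))
  if (length(overrides) == 0) return(landmarks)
  unknown <- setdiff(names(overrides), LANDMARK_NAMES)
  if (length(unknown) > 0) {
    stop("unknown landmark name(s) in overrides: ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) {
    p <- as.numeric(overrides[[nm]])
    stopifnot(length(p) == 2, all(is.finite(p)))
    if (!is.null(bounds) &&
        (p[1] < 1 || p[1] > bounds[2] || p[2] < 1 || p[2] > bounds[1])) {
      stop(sprintf("override for %s is outside the raster bounds", nm))
    }
    landmarks$points[[nm]] <- p
    landmarks$provenance[[nm]] <- "overridden"
  }
  check_landmark_order(landmarks)
  landmarks
}

# The four defining lines, recomputed from the point set.
#' @keywords internal
landmark_lines <- function(lm) {
  p <- lm$points
  need <- function(nms) {
    miss <- nms[!nms %in% names(p)]
    if (length(miss) > 0) {
      stop("missing landmark(s): ", paste(miss, collapse = ", "))
    }
  }
  need(LANDMARK_NAMES)
  list(talar = line_through(p$talar_body_mid, p$talar_neck_mid),
       metatarsal = line_through(p$mt1_proximal_mid, p$mt1_distal_mid),
       calc_tangent = line_through(p$calc_tangent_posterior,
                                   p$calc_tangent_anterior),
       wbs = line_through(p$wbs_posterior, p$wbs_anterior))
}
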