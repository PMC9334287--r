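#' Signed declination of a line relative to a reference
#'
#' The signed angle, in degrees, from the reference direction to the line
#' direction, positive when the line tilts plantarward (toward +y, i.e.
#' toward the ground in raster coordinates) relative to the reference.
#' The default reference is the horizontal (+x). Range (-90, 90].
#'
#' @param line \code{\link{foot_line}}.
#' @param reference \code{\link{foot_line}}; default horizontal.
#' @return Signed degrees.
#' @export
declination <- function(line, reference = foot_line(c(0, 0), c(1, 0))) {
  stopifnot(inherits(line, "foot_line"), inherits(reference, "foot_line"))
  d <- line$direction; r <- reference$direction
  ang <- atan2(d[1] * r[2] - d[2] * r[1], d[1] * r[1] + d[2] * r[2])
  # cross = r x d reversed above: atan2(cross(d, r)) gives r-to-d with sign
  deg <- -ang * 180 / pi
  if (deg <= -90) deg <- deg + 180
  if (deg > 90) deg <- deg - 180
  deg
}

#' Meary angle (talo-first metatarsal angle)
#'
#' The angle between the long axis of the talus and the long axis of the
#' first metatarsus. Computed as the metatarsal declination minus the talar
#' declination (both relative to the horizontal), so a collapsed medial
#' arch — talus tilted plantarward more steeply than the metatarsus — gives
#' a negative angle, consistent with the pes-planus cutoff of less than
#' -4 degrees. \code{sign_flip = TRUE} exposes the opposite convention.
#'
#' @param talar,metatarsal Canonical-orientation \code{\link{foot_line}}s
#'   (dx > 0).
#' @param sign_flip Report the angle with the opposite sign.
#' @return Signed degrees.
#' @export
meary_angle <- function(talar, metatarsal, sign_flip = FALSE) {
  ang <- declination(metatarsal) - declination(talar)
  if (sign_flip) -ang else ang
}

#' Calcaneal pitch
#'
#' The acute angle between the line outlining the inferior border of the
#' calcaneus and the weightbearing surface, in [0, 90). A calcaneal border
#' tilting below the weightbearing surface (non-physiologic) still yields
#' its acute magnitude, with a warning.
#'
#' @param inferior_tangent,wbs \code{\link{foot_line}}s.
#' @return Degrees in [0, 90).
#' @export
calcaneal_pitch <- function(inferior_tangent, wbs) {
  ang <- declination(inferior_tangent, reference = wbs)
  if (ang > 0.5) {
    # tangent tilts plantarward of the ground line going anteriorly:
    # the calcaneus would dip below its own support
    warning("inferior calcaneal border tilts below the weightbearing surface; reporting the acute magnitude")
  }
  abs(ang)
}

#' Classify pes planus from the two angles
#'
#' Applies the standard radiographic cutoffs with strict inequalities:
#' PP by the Meary criterion iff the Meary angle is less than -4 degrees;
#' PP by the calcaneal-pitch criterion iff the pitch is less than
#' 18 degrees. Boundary values classify as non-PP.
#'
#' @param meary Meary angle, signed degrees.
#' @param pitch Calcaneal pitch, degrees.
#' @param meary_cutoff,pitch_cutoff Decision thresholds.
#' @return List with logicals \code{pp_by_meary}, \code{pp_by_pitch}.
#' @export
classify_pp <- function(meary, pitch, meary_cutoff = -4, pitch_cutoff = 18) {
  if (!all(is.finite(c(meary, pitch)))) stop("angles must be finite")
  list(pp_by_meary = meary < meary_cutoff, pp_by_pitch = pitch < pitch_cutoff)
}

#' Measure a foot from its bone masks
#'
#' The full measurement pipeline: landmark extraction, optional programmatic
#' landmark overrides, angle computation from the (possibly adjusted)
#' landmark set, and cutoff classification. Left-foot masks are mirrored
#' into canonical orientation first and landmark coordinates mapped back to
#' the input frame in the result.
#'
#' @param mask Integer label mask with talus, first metatarsus, calcaneus.
#' @param overrides Optional named list of c(x, y) landmark replacements,
#'   in the input (unmirrored) frame.
#' @param side "right" or "left".
#' @param sign_flip Report the Meary angle under the opposite sign
#'   convention.
#' @param meary_cutoff,pitch_cutoff Classification thresholds.
#' @param body_station,neck_station,junction_ratio Landmark tuning
#'   parameters (see \code{\link{extract_landmarks}}).
#' @return Object of class \code{foot_measurement}: list with \code{meary},
#'   \code{pitch}, \code{pp_by_meary}, \code{pp_by_pitch},
#'   \code{landmarks} (input frame), \code{side},
#'   \code{landmark_source} ("automatic", "adjusted" or "manual").
#' @export
measure_foot <- function(mask, overrides = NULL, side = c("right", "left"),
                         sign_flip = FALSE, meary_cutoff = -4,
                         pitch_cutoff = 18, body_station = 0.35,
                         neck_station = 0.78, junction_ratio = 1.20) {
  side <- match.arg(side)
  w <- ncol(mask)
  canon <- if (side == "left") mirror_raster(mask) else mask
  mirror_pts <- function(pts) {
    lapply(pts, function(p) c(mirror_x(p[1], w), p[2]))
  }
  canon_overrides <- overrides
  if (side == "left" && length(overrides) > 0) {
    canon_overrides <- mirror_pts(overrides)
  }
  full_manual <- length(canon_overrides) > 0 &&
    all(LANDMARK_NAMES %in% names(canon_overrides))
  if (full_manual) {
    lm <- foot_landmarks(canon_overrides[LANDMARK_NAMES],
                         provenance = "manual")
    check_landmark_order(lm)
  } else {
    lm <- extract_landmarks(canon, body_station = body_station,
                            neck_station = neck_station,
                            junction_ratio = junction_ratio)
    if (length(canon_overrides) > 0) {
      lm <- apply_overrides(lm, canon_overrides, bounds = dim(mask))
    }
  }
  ln <- landmark_lines(lm)
  meary <- meary_angle(ln$talar, ln$metatarsal, sign_flip = sign_flip)
  pitch <- calcaneal_pitch(ln$calc_tangent, ln$wbs)
  cls <- classify_pp(meary, pitch, meary_cutoff, pitch_cutoff)
  out_lm <- lm
  if (side == "left") out_lm$points <- mirror_pts(lm$points)
  src <- if (full_manual) "manual"
         else if (any(out_lm$provenance == "overridden")) "adjusted"
         else "automatic"
  structure(list(meary = meary, pitch = pitch,
                 pp_by_meary = cls$pp_by_meary,
                 pp_by_pitch = cls$pp_by_pitch,
                 landmarks = out_lm, side = side, landmark_source = src),
            class = "foot_measurement")
}

#' @export
print.foot_measurement <- function(x, ...) {
  cat(sprintf("<foot_measurement> %s foot (%s landmarks)\n", x$side,
              x$landmark_source))
  cat(sprintf("  Meary angle:     %7.2f deg  -> %s\n", x$meary,
              if (x$pp_by_meary) "pes planus" else "non-pes planus"))
  cat(sprintf("  Calcaneal pitch: %7.2f deg  -> %s\n", x$pitch,
              if (x$pp_by_pitch) "pes planus" else "non-pes planus"))
  invisible(x)
}
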