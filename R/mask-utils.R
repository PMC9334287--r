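#' Bone label codes used throughout the package
#'
#' Label masks are integer matrices (rows = y, top to bottom; columns = x,
#' left to right) whose pixel values identify the segmented structure:
#' 0 background, 1 talus, 2 first metatarsus, 3 calcaneus.
#'
#' @format Named integer vector of length 4.
#' @export
BONE_LABELS <- c(background = 0L, talus = 1L, first_metatarsus = 2L,
                 calcaneus = 3L)

#' @keywords internal
label_name <- function(label) {
  nm <- names(BONE_LABELS)[match(label, BONE_LABELS)]
  if (is.na(nm)) as.character(label) else nm
}

#' Validate a bone label mask
#'
#' Checks that a raster contains only the labels 0-3 and that each bone
#' present forms a single 4-connected component. Fragmented bones are
#' tolerated with a warning because real segmenters can split a bone;
#' downstream geometry then uses the largest fragment.
#'
#' @param mask Integer matrix of label values.
#' @param warn_fragments Warn (rather than fail) when a bone label splits
#'   into several 4-connected components.
#' @return The mask, invisibly, as an integer matrix.
#' @export
validate_mask <- function(mask, warn_fragments = TRUE) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), BONE_LABELS)
  if (length(bad) > 0) {
    stop("mask contains labels outside {0,1,2,3}: ",
         paste(sort(bad), collapse = ", "))
  }
  for (lab in setdiff(unique(as.vector(mask)), 0L)) {
    nc <- n_components4(mask == lab)
    if (nc > 1 && warn_fragments) {
      warning(sprintf("label %d (%s) is split into %d components; largest will be used",
                      lab, label_name(lab), nc))
    }
  }
  invisible(mask)
}

# 4-connected flood fill from a seed index; returns logical matrix of the
# reached component. Iterative dilation restricted to `m`, vectorised.
#' @keywords internal
flood4 <- function(m, seed_idx) {
  h <- nrow(m); w <- ncol(m)
  comp <- matrix(FALSE, h, w)
  comp[seed_idx] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-h, ]
    grown[-h, ] <- grown[-h, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -w]
    grown[, -w] <- grown[, -w] | comp[, -1]
    grown <- grown & m
    if (sum(grown) == sum(comp)) return(comp)
    comp <- grown
  }
}

# Crop a logical matrix to the bounding box of its TRUE cells.
#' @keywords internal
crop_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  list(m = m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       rows = rows, cols = cols)
}

#' @keywords internal
n_components4 <- function(m) {
  if (!any(m)) return(0L)
  cb <- crop_bbox(m)
  remaining <- cb$m
  n <- 0L
  while (any(remaining)) {
    comp <- flood4(remaining, which(remaining)[1])
    remaining <- remaining & !comp
    n <- n + 1L
  }
  n
}

# Largest 4-connected component of a logical matrix.
#' @keywords internal
largest_component4 <- function(m) {
  if (!any(m)) return(m)
  cb <- crop_bbox(m)
  best <- NULL; best_n <- -1L
  remaining <- cb$m
  while (any(remaining)) {
    comp <- flood4(remaining, which(remaining)[1])
    if (sum(comp) > best_n) { best <- comp; best_n <- sum(comp) }
    remaining <- remaining & !comp
  }
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[cb$rows[1]:cb$rows[2], cb$cols[1]:cb$cols[2]] <- best
  out
}

# Inner boundary (bone pixels with a 4-neighbour outside) and outer boundary
# (background pixels 4-adjacent to the bone).
#' @keywords internal
boundary4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  nb <- matrix(0L, h, w)
  nb[-1, ] <- nb[-1, ] + m[-h, ]
  nb[-h, ] <- nb[-h, ] + m[-1, ]
  nb[, -1] <- nb[, -1] + m[, -w]
  nb[, -w] <- nb[, -w] + m[, -1]
  edge <- matrix(FALSE, h, w)
  edge[1, ] <- TRUE; edge[h, ] <- TRUE; edge[, 1] <- TRUE; edge[, w] <- TRUE
  list(inner = m & (nb < 4L | edge), outer = !m & nb > 0L)
}

# Boundary pixels for hull work: 8-connected outline (pixel of the label with
# at least one of its 8 neighbours outside the label or on the image edge).
#' @keywords internal
outline8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  all8 <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] &
    pad[1:h, 1:w] & pad[1:h, 3:(w + 2)] &
    pad[3:(h + 2), 1:w] & pad[3:(h + 2), 3:(w + 2)]
  m & !all8
}

# Pixel coordinates (x = column, y = row) of TRUE cells.
#' @keywords internal
mask_xy <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Mirror a raster left-right
#'
#' Flips the columns of an image or label mask, converting between left- and
#' right-foot orientation. All geometry in this package assumes the canonical
#' orientation with toes pointing toward +x (rightward); left-foot inputs are
#' mirrored before landmark extraction and results mapped back.
#'
#' @param m Matrix (image or mask).
#' @return Matrix of the same shape with columns reversed.
#' @export
mirror_raster <- function(m) m[, ncol(m):1, drop = FALSE]

#' Mirror an x coordinate across a raster of given width
#' @param x X coordinate(s) in pixels.
#' @param width Raster width in pixels.
#' @return Mirrored x coordinate(s).
#' @export
mirror_x <- function(x, width) width + 1 - x

#' Rigidly rotate a label mask about the image centre
#'
#' Nearest-neighbour inverse-mapped rotation, used to test rotational
#' invariance of the angle pipeline. Positive angles rotate the +x axis
#' toward +y (clockwise on screen with y pointing down).
#'
#' @param mask Integer label matrix.
#' @param degrees Rotation angle.
#' @return Rotated mask of the same shape.
#' @export
rotate_mask <- function(mask, degrees) {
  h <- nrow(mask); w <- ncol(mask)
  th <- degrees * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), times = w), h, w) - cy
  # inverse rotation of each destination pixel back into the source
  sx <- round(cos(th) * xs + sin(th) * ys + cx)
  sy <- round(-sin(th) * xs + cos(th) * ys + cy)
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  out <- matrix(0L, h, w)
  out[ok] <- mask[cbind(as.vector(sy[ok]), as.vector(sx[ok]))]
  out
}

#' Translate a label mask by whole pixels
#'
#' @param mask Integer label matrix.
#' @param dx,dy Shift in pixels (x rightward, y downward). Content shifted
#'   outside the canvas is dropped; vacated pixels become background.
#' @return Shifted mask of the same shape.
#' @export
translate_mask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  src_x <- seq_len(w) - dx; src_y <- seq_len(h) - dy
  okx <- src_x >= 1 & src_x <= w; oky <- src_y >= 1 & src_y <= h
  out[oky, okx] <- mask[src_y[oky], src_x[okx]]
  out
}

#' Rescale a label mask by a uniform factor
#'
#' Nearest-neighbour scaling about the top-left origin onto a canvas of the
#' scaled size; used to test scale invariance of landmark geometry.
#'
#' @param mask Integer label matrix.
#' @param factor Positive scale factor.
#' @return Scaled mask.
#' @export
scale_mask <- function(mask, factor) {
  stopifnot(factor > 0)
  h2 <- max(1L, round(nrow(mask) * factor))
  w2 <- max(1L, round(ncol(mask) * factor))
  # ceiling mapping makes integer upscaling exact pixel replication
  sy <- pmin(nrow(mask), pmax(1L, ceiling(seq_len(h2) / factor - 1e-9)))
  sx <- pmin(ncol(mask), pmax(1L, ceiling(seq_len(w2) / factor - 1e-9)))
  mask[sy, sx, drop = FALSE]
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
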