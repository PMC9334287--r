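# Shared fixtures: simple geometric masks, small ratings tables, and a
# minimal DICOM writer used to exercise the radiograph reader.

rect_mask <- function(h = 120, w = 160, label = 1L,
                      y0 = 51, y1 = 70, x0 = 31, x1 = 130) {
  m <- matrix(0L, h, w)
  m[y0:y1, x0:x1] <- as.integer(label)
  m
}

disk_mask <- function(h = 120, w = 120, label = 1L, r = 40) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  m <- matrix(0L, h, w)
  m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- as.integer(label)
  m
}

# 6x3 ratings table with known ICCs (frozen oracle values recomputed by
# explicit sums in the tests themselves)
ratings_6x3 <- function() {
  matrix(c(9, 10, 8,
           6, 7, 5,
           8, 8, 9,
           7, 5, 6,
           10, 12, 11,
           6, 4, 5), 6, 3, byrow = TRUE)
}

# Long-format ratings data frame for a complete crossed design with a
# reader-specific bias in one condition.
simulate_ratings <- function(n_subjects = 20, raters = 1:3, sessions = 1:2,
                             bias = c(-3, 0, 3), noise_without = 2,
                             noise_with = 0.8, seed = 42) {
  set.seed(seed)
  truth <- runif(n_subjects, -25, 15)
  grid <- expand.grid(subject = seq_len(n_subjects), rater = raters,
                      session = sessions,
                      condition = c("without_algorithm", "with_algorithm"),
                      stringsAsFactors = FALSE)
  is_without <- grid$condition == "without_algorithm"
  grid$value <- truth[grid$subject] +
    ifelse(is_without, bias[match(grid$rater, raters)], 0) +
    rnorm(nrow(grid), 0, ifelse(is_without, noise_without, noise_with))
  attr(grid, "truth") <- truth
  grid
}

# --- minimal DICOM writer (little endian) for reader tests ---

dicom_bytes_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
dicom_bytes_u32 <- function(x) {
  as.raw(c(x %% 256L, (x %/% 256L) %% 256L, (x %/% 65536L) %% 256L,
           (x %/% 16777216L) %% 256L))
}

dicom_element_explicit <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(dicom_bytes_u16(group), dicom_bytes_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), dicom_bytes_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, dicom_bytes_u16(length(value_raw)), value_raw)
  }
}

dicom_element_implicit <- function(group, elem, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, charToRaw(" "))
  c(dicom_bytes_u16(group), dicom_bytes_u16(elem),
    dicom_bytes_u32(length(value_raw)), value_raw)
}

# pixels: integer matrix (rows = y), row-major in the file as DICOM stores
write_minimal_dicom <- function(path, pixels, photometric = "MONOCHROME2",
                                bits = 8L, spacing = NULL, n_frames = NULL,
                                implicit = FALSE, truncate_at = NULL) {
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta <- dicom_element_explicit(0x0002, 0x0010, "UI", charToRaw(ts))
  el <- if (implicit) {
    function(g, e, vr, v) dicom_element_implicit(g, e, v)
  } else {
    dicom_element_explicit
  }
  rows <- nrow(pixels); cols <- ncol(pixels)
  body <- c(
    el(0x0028, 0x0002, "US", dicom_bytes_u16(1L)),
    el(0x0028, 0x0004, "CS", charToRaw(photometric)),
    if (!is.null(n_frames)) {
      el(0x0028, 0x0008, "IS", charToRaw(as.character(n_frames)))
    },
    el(0x0028, 0x0010, "US", dicom_bytes_u16(rows)),
    el(0x0028, 0x0011, "US", dicom_bytes_u16(cols)),
    if (!is.null(spacing)) {
      el(0x0028, 0x0030, "DS",
         charToRaw(paste(format(spacing), collapse = "\\")))
    },
    el(0x0028, 0x0100, "US", dicom_bytes_u16(bits)),
    el(0x0028, 0x0101, "US", dicom_bytes_u16(bits)),
    el(0x0028, 0x0103, "US", dicom_bytes_u16(0L))
  )
  vals <- as.integer(t(pixels))   # row-major
  px <- if (bits == 8L) {
    as.raw(vals)
  } else {
    as.raw(as.vector(rbind(vals %% 256L, vals %/% 256L)))
  }
  pixel_el <- if (implicit) {
    dicom_element_implicit(0x7FE0, 0x0010, px)
  } else {
    dicom_element_explicit(0x7FE0, 0x0010, if (bits == 8L) "OB" else "OW", px)
  }
  out <- c(rep(as.raw(0), 128), charToRaw("DICM"), meta, body, pixel_el)
  if (!is.null(truncate_at)) out <- out[seq_len(truncate_at)]
  writeBin(out, path)
  invisible(path)
}
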