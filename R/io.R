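#' Read a radiograph (PNG or single-frame monochrome DICOM)
#'
#' PNG files must be 8- or 16-bit grayscale; DICOM files must be
#' single-frame monochrome in implicit- or explicit-VR little-endian
#' transfer syntax (the uncompressed formats produced by standard export).
#' MONOCHROME1 photometric interpretation is inverted on load so higher
#' values are always brighter. Pixel spacing (mm/pixel) is returned when
#' the file carries it; angle computation never needs it, so it is
#' metadata only.
#'
#' @param path File path; format detected from content.
#' @return List with \code{pixels} (numeric matrix, rows = y) and
#'   \code{spacing} (numeric c(row, col) mm/pixel, or NULL).
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head <- readBin(path, "raw", 256)
  if (length(head) >= 8 &&
      identical(head[1:8], as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A,
                                    0x1A, 0x0A)))) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) stop("expected a grayscale PNG, got ",
                                    dim(img)[3], " channels")
    return(list(pixels = img * 255, spacing = NULL))
  }
  if (length(head) >= 132 &&
      identical(rawToChar(head[129:132]), "DICM")) {
    return(read_dicom_monochrome(path))
  }
  stop("unreadable file (not PNG and not DICOM): ", path)
}

# --- minimal DICOM parser: single-frame monochrome, little endian ---

#' @keywords internal
read_dicom_monochrome <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 200) stop("truncated DICOM file: ", path)
  pos <- 133L  # after 128-byte preamble + "DICM"
  u16 <- function(p) sum(as.integer(raw[p:(p + 1)]) * c(1, 256))
  u32 <- function(p) sum(as.integer(raw[p:(p + 3)]) * c(1, 256, 65536, 16777216))
  need <- function(p, nbytes) {
    if (p + nbytes - 1 > length(raw)) stop("truncated DICOM file: ", path)
  }

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  explicit <- TRUE  # file meta group is always explicit VR
  transfer_syntax <- NULL

  repeat {
    if (pos + 7 > length(raw)) break
    group <- u16(pos); elem <- u16(pos + 2L)
    # switch to the dataset transfer syntax after the meta group
    if (group != 2L && !is.null(transfer_syntax)) {
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      transfer_syntax <- NULL  # decided once
    }
    if (explicit) {
      need(pos, 8)
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        need(pos, 12)
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      need(pos, 8)
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (identical(vr, "SQ") || len == 4294967295) {
      stop("unsupported DICOM: sequences / undefined lengths")
    }
    body_start <- pos + hdr
    need(body_start, max(len, 1L) - (len == 0))
    key <- sprintf("%04x,%04x", group, elem)
    value_raw <- if (len > 0) raw[body_start:(body_start + len - 1L)] else raw(0)
    tags[[key]] <- value_raw
    if (key == "0002,0010") {
      transfer_syntax <- sub("\\s+$", "",
                             rawToChar(value_raw[value_raw != as.raw(0)]))
      if (!transfer_syntax %in% c("1.2.840.10008.1.2",
                                  "1.2.840.10008.1.2.1")) {
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
      }
    }
    if (key == "7fe0,0010") break
    pos <- body_start + len
  }

  str_tag <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    s <- rawToChar(v[v != as.raw(0)])
    sub("\\s+$", "", sub("^\\s+", "", s))
  }
  int_tag <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    sum(as.integer(v) * 256^(seq_along(v) - 1))
  }

  nframes <- str_tag("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1) {
    stop("multi-frame DICOM not supported (", nframes, " frames)")
  }
  rows <- int_tag("0028,0010"); cols <- int_tag("0028,0011")
  bits_alloc <- int_tag("0028,0100")
  bits_stored <- int_tag("0028,0101")
  photometric <- str_tag("0028,0004")
  if (is.null(rows) || is.null(cols) || is.null(bits_alloc)) {
    stop("DICOM missing Rows/Columns/BitsAllocated")
  }
  if (is.null(bits_stored)) bits_stored <- bits_alloc
  if (!bits_alloc %in% c(8L, 16L)) {
    stop("unsupported BitsAllocated: ", bits_alloc)
  }
  if (!is.null(photometric) &&
      !photometric %in% c("MONOCHROME1", "MONOCHROME2")) {
    stop("unsupported PhotometricInterpretation: ", photometric)
  }
  px_raw <- tags[["7fe0,0010"]]
  if (is.null(px_raw)) stop("DICOM has no PixelData")
  npix <- rows * cols
  if (bits_alloc == 8L) {
    if (length(px_raw) < npix) stop("truncated PixelData")
    vals <- as.integer(px_raw[seq_len(npix)])
  } else {
    if (length(px_raw) < 2 * npix) stop("truncated PixelData")
    m <- matrix(as.integer(px_raw[seq_len(2 * npix)]), nrow = 2)
    vals <- m[1, ] + 256L * m[2, ]
  }
  if (identical(photometric, "MONOCHROME1")) {
    vals <- (2^bits_stored - 1) - vals
  }
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  spacing <- NULL
  sp <- str_tag("0028,0030")
  if (is.null(sp)) sp <- str_tag("0018,1164")
  if (!is.null(sp)) {
    parts <- suppressWarnings(as.numeric(strsplit(sp, "\\\\")[[1]]))
    if (length(parts) == 2 && all(is.finite(parts))) spacing <- parts
  }
  list(pixels = pixels, spacing = spacing)
}

#' Read a bone label mask from an indexed PNG
#'
#' The mask is stored as an 8-bit grayscale PNG whose raw byte values are
#' the bone labels (0 background, 1 talus, 2 first metatarsus,
#' 3 calcaneus). Any other value is an error. A bone split into several
#' 4-connected components is accepted with a warning; downstream geometry
#' uses the largest fragment.
#'
#' @param path PNG file path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) stop("mask PNG must be single-channel")
  mask <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  validate_mask(mask)
  mask
}

#' Write a bone label mask as an indexed PNG
#'
#' @param mask Integer label matrix (values 0-3).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask, warn_fragments = FALSE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

MEASUREMENT_COLUMNS <- c("subject_id", "side", "meary", "pitch",
                         "pp_by_meary", "pp_by_pitch", "landmark_source")

#' Write measurement records to CSV
#'
#' One row per measured foot, stable column order
#' (subject_id, side, meary, pitch, pp_by_meary, pp_by_pitch,
#' landmark_source), angles serialized at 2-decimal precision. The writer
#' is deterministic: identical inputs give byte-identical files.
#'
#' @param records Data frame with the measurement columns, or a list of
#'   \code{foot_measurement} objects paired with \code{subject_id}s via
#'   \code{\link{measurement_record}}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  if (!is.null(records) && nrow(records) > 0) {
    stopifnot(all(MEASUREMENT_COLUMNS %in% names(records)))
    stopifnot(all(is.finite(records$meary)), all(is.finite(records$pitch)))
    records <- records[, MEASUREMENT_COLUMNS]
    records$meary <- sprintf("%.2f", records$meary)
    records$pitch <- sprintf("%.2f", records$pitch)
  } else {
    records <- as.data.frame(stats::setNames(
      replicate(length(MEASUREMENT_COLUMNS), character(0),
                simplify = FALSE), MEASUREMENT_COLUMNS))
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a measurement record row
#'
#' @param measurement \code{foot_measurement}.
#' @param subject_id Subject identifier.
#' @return One-row data frame in the measurement CSV layout.
#' @export
measurement_record <- function(measurement, subject_id) {
  stopifnot(inherits(measurement, "foot_measurement"))
  data.frame(subject_id = subject_id, side = measurement$side,
             meary = measurement$meary, pitch = measurement$pitch,
             pp_by_meary = measurement$pp_by_meary,
             pp_by_pitch = measurement$pp_by_pitch,
             landmark_source = measurement$landmark_source,
             stringsAsFactors = FALSE)
}

#' Read measurement records from CSV
#'
#' @param path CSV written by \code{\link{write_measurements}}.
#' @return Data frame; duplicate (subject_id, side) rows are an error.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop("measurement CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(df$subject_id, df$side)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, side) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df$pp_by_meary <- as.logical(df$pp_by_meary)
  df$pp_by_pitch <- as.logical(df$pp_by_pitch)
  df
}

#' Read a reader-ratings table from long-format CSV
#'
#' Expects columns subject, rater, session, condition, value with
#' condition in {with_algorithm, without_algorithm}. Each (subject, rater,
#' session, condition) cell must occur at most once; cells missing from
#' the complete crossed design are reported in the \code{missing_cells}
#' attribute.
#'
#' @param path CSV file path.
#' @return Data frame of class \code{ratings_long}.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "rater", "session", "condition", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("ratings CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$condition), c("with_algorithm",
                                         "without_algorithm"))
  if (length(bad) > 0) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  }
  key <- paste(df$subject, df$rater, df$session, df$condition)
  if (anyDuplicated(key)) {
    stop("duplicated ratings cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(!is.finite(df$value))) stop("non-finite rating values")
  full <- expand.grid(subject = unique(df$subject),
                      rater = unique(df$rater),
                      session = unique(df$session),
                      condition = unique(df$condition),
                      stringsAsFactors = FALSE)
  full_key <- paste(full$subject, full$rater, full$session, full$condition)
  missing_cells <- full[!full_key %in% key, , drop = FALSE]
  rownames(missing_cells) <- NULL
  structure(df, missing_cells = missing_cells,
            class = c("ratings_long", "data.frame"))
}

#' Pivot long ratings into a subjects x raters (or sessions) matrix
#'
#' @param ratings \code{ratings_long} data frame.
#' @param condition Condition to select.
#' @param session Session to select when pivoting over raters; ignored when
#'   \code{by = "session"}.
#' @param rater Rater to select when pivoting over sessions.
#' @param by "rater" (columns = raters, for inter-observer ICC) or
#'   "session" (columns = sessions for one rater, for intra-observer ICC).
#' @return Numeric matrix with subjects as (named) rows.
#' @export
ratings_matrix <- function(ratings, condition, session = NULL, rater = NULL,
                           by = c("rater", "session")) {
  by <- match.arg(by)
  df <- ratings[ratings$condition == condition, , drop = FALSE]
  if (by == "rater") {
    if (!is.null(session)) df <- df[df$session == session, , drop = FALSE]
    cols <- "rater"
  } else {
    if (is.null(rater)) stop("rater required when pivoting by session")
    df <- df[df$rater == rater, , drop = FALSE]
    cols <- "session"
  }
  if (nrow(df) == 0) stop("no ratings for the requested slice")
  subjects <- sort(unique(df$subject))
  levels_c <- sort(unique(df[[cols]]))
  m <- matrix(NA_real_, length(subjects), length(levels_c),
              dimnames = list(as.character(subjects),
                              as.character(levels_c)))
  m[cbind(match(df$subject, subjects), match(df[[cols]], levels_c))] <- df$value
  if (any(is.na(m))) {
    stop("incomplete crossed design for the requested ICC slice")
  }
  m
}

#' Write a landmark set to JSON
#'
#' Schema: object mapping each landmark name to
#' \code{{"x": px, "y": px, "provenance": "automatic"|"overridden"|"manual"}}.
#'
#' @param landmarks \code{\link{foot_landmarks}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "foot_landmarks"))
  obj <- lapply(names(landmarks$points), function(nm) {
    p <- landmarks$points[[nm]]
    list(x = p[1], y = p[2], provenance = landmarks$provenance[[nm]])
  })
  names(obj) <- names(landmarks$points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a landmark set from JSON
#' @param path JSON written by \code{\link{write_landmarks}}.
#' @return \code{\link{foot_landmarks}}.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path)
  pts <- lapply(obj, function(o) c(o$x, o$y))
  prov <- vapply(obj, function(o) o$provenance %||% "automatic",
                 character(1))
  foot_landmarks(pts, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
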