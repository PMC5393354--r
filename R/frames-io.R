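#' Write a cine stack to disk
#'
#' Two on-disk dialects are supported, both with a JSON sidecar holding
#' `{"rows","cols","pitch_mm","frames","energy_mode","frame_rate_fps"}`:
#'
#' * `tiff_stack`: one multi-page 16-bit grayscale TIFF (`<stem>.tiff`).
#'   Values must be integers in \[0, 65535\] (ADU counts).
#' * `raw_binary`: unsigned 16-bit little-endian, row-major, frames
#'   concatenated (`<stem>.bin`), matching typical flat-panel streaming
#'   output.
#'
#' @param stack A [cine_stack()].
#' @param stem Path stem; `<stem>.tiff`/`<stem>.bin` and `<stem>.json` are
#'   written.
#' @param format `"tiff_stack"` or `"raw_binary"`.
#' @return `stem`, invisibly.
#' @export
write_stack <- function(stack, stem, format = c("tiff_stack", "raw_binary")) {
  format <- match.arg(format)
  f1 <- stack$frames[[1L]]
  vals <- lapply(stack$frames, function(f) round(unclass(f)))
  rng <- range(unlist(lapply(vals, range)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("stack values outside the 16-bit range [0, 65535]: ",
         rng[1], "..", rng[2])
  meta <- list(
    rows = nrow(f1), cols = ncol(f1), pitch_mm = pitch_mm(f1),
    frames = length(stack$frames),
    energy_mode = if (is.null(stack$mode)) NA else stack$mode$name,
    frame_rate_fps = stack$frame_rate_fps
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (format == "tiff_stack") {
    tiff::writeTIFF(lapply(vals, function(m) m / 65535),
                    paste0(stem, ".tiff"), bits.per.sample = 16L)
  } else {
    con <- file(paste0(stem, ".bin"), "wb")
    on.exit(close(con))
    for (m in vals) {
      # row-major: write the transpose so rows are contiguous
      writeBin(as.integer(t(m)), con, size = 2L, endian = "little")
    }
  }
  invisible(stem)
}

#' Read a cine stack from disk
#'
#' Counterpart of [write_stack()]; values round-trip bit-exactly for both
#' dialects. The raw-binary dialect requires the JSON sidecar for
#' dimensions, frame count and geometry; a file truncated mid-frame is
#' rejected with the index of the incomplete frame.
#'
#' @param stem Path stem as given to [write_stack()].
#' @param format `"tiff_stack"` or `"raw_binary"`.
#' @return A [cine_stack()].
#' @export
read_stack <- function(stem, format = c("tiff_stack", "raw_binary")) {
  format <- match.arg(format)
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mk <- function(m) frame_image(m, pitch_mm = meta$pitch_mm, units = "ADU")
  if (format == "tiff_stack") {
    path <- paste0(stem, ".tiff")
    if (!file.exists(path)) stop("missing file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (i in seq_along(pages)) {
      if (nrow(pages[[i]]) != meta$rows || ncol(pages[[i]]) != meta$cols)
        stop("frame ", i, " size ", nrow(pages[[i]]), "x", ncol(pages[[i]]),
             " does not match sidecar ", meta$rows, "x", meta$cols)
    }
    frames <- lapply(pages, mk)
  } else {
    path <- paste0(stem, ".bin")
    if (!file.exists(path)) stop("missing file: ", path)
    per_frame <- meta$rows * meta$cols
    n_avail <- file.size(path) / 2
    frames <- vector("list", meta$frames)
    con <- file(path, "rb")
    on.exit(close(con))
    for (i in seq_len(meta$frames)) {
      v <- readBin(con, "integer", n = per_frame, size = 2L,
                   signed = FALSE, endian = "little")
      if (length(v) < per_frame)
        stop("file truncated: frame ", i, " is incomplete (",
             length(v), " of ", per_frame, " pixels; file holds ",
             floor(n_avail), " values)")
      frames[[i]] <- mk(matrix(v, meta$rows, meta$cols, byrow = TRUE))
    }
  }
  mode <- if (is.null(meta$energy_mode) || is.na(meta$energy_mode)) NULL
          else energy_mode(meta$energy_mode)
  cine_stack(frames, frame_rate_fps = meta$frame_rate_fps, mode = mode)
}

#' Write a float grid as CSV matrix + JSON metadata
#'
#' Full-precision text format for non-integer grids (correction fields,
#' kernels, fluence and dose maps): `<stem>.csv` holds the matrix,
#' `<stem>.json` the geometry, units and any extra metadata.
#'
#' @param img A `frame_image` (or kernel/dose map; any matrix with pitch).
#' @param stem Path stem.
#' @param extra Named list merged into the JSON metadata.
#' @return `stem`, invisibly.
#' @export
write_frame <- function(img, stem, extra = list()) {
  meta <- c(list(rows = nrow(img), cols = ncol(img),
                 pitch_mm = pitch_mm(img),
                 units = attr(img, "units")), extra)
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    format(unclass(img), digits = 17, scientific = TRUE, trim = TRUE),
    paste0(stem, ".csv"),
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(stem)
}

#' Read a float grid written by [write_frame()]
#' @param stem Path stem.
#' @return A `frame_image`; the JSON metadata is attached as attribute
#'   `meta`.
#' @export
read_frame <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ",",
                                   header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  units <- if (is.null(meta$units) || is.na(meta$units)) "relative" else meta$units
  img <- frame_image(m, pitch_mm = meta$pitch_mm, units = units)
  attr(img, "meta") <- meta
  img
}

#' Export a profile as CSV
#' @param profile Tibble with `position_mm`, `value`.
#' @param path Output CSV path (columns `position_mm,value`).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile[, c("position_mm", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
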