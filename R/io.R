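#' Read / write a blood-flow frame as 32-bit float TIFF
#'
#' Blood-flow frames are single-channel rasters of strictly positive
#' relative perfusion values, stored as uncompressed little-endian
#' IEEE-float TIFF (bits per sample 32, sample format 3) so device-scale
#' values survive unscaled: reading a written file back reproduces the
#' stored 32-bit values exactly. Positivity is validated on both read and
#' write. Foreign TIFFs (integer or multichannel) are detected and
#' rejected with a format error.
#'
#' @param frame H x W numeric matrix of positive values.
#' @param path TIFF path.
#' @return `read_flow_frame` returns the H x W matrix.
#' @export
write_flow_frame <- function(frame, path) {
  check_flow_values(frame)
  H <- nrow(frame); W <- ncol(frame)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  writeChar("II", con, nchars = 2, eos = NULL); w2(42L); w4(8L)
  n_tags <- 10L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  w2(n_tags)
  tag(256L, 3L, 1L, W)                    # ImageWidth
  tag(257L, 3L, 1L, H)                    # ImageLength
  tag(258L, 3L, 1L, 32L)                  # BitsPerSample
  tag(259L, 3L, 1L, 1L)                   # Compression: none
  tag(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_offset)          # StripOffsets
  tag(277L, 3L, 1L, 1L)                   # SamplesPerPixel
  tag(278L, 3L, 1L, H)                    # RowsPerStrip
  tag(279L, 4L, 1L, H * W * 4L)           # StripByteCounts
  tag(339L, 3L, 1L, 3L)                   # SampleFormat: IEEE float
  w4(0L)                                  # no further IFD
  # row-major pixel order
  writeBin(as.numeric(t(frame)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_flow_frame
#' @export
read_flow_frame <- function(path) {
  tags <- read_tiff_tags(path)
  if (!is.null(tags) && identical(tags[["339"]], 3L) &&
      identical(tags[["258"]], 32L) && identical(tags[["259"]], 1L)) {
    spp <- tags[["277"]]
    if (!is.null(spp) && spp != 1L)
      stop(sprintf("expected a single-channel TIFF, found %d channels", spp),
           call. = FALSE)
    H <- tags[["257"]]; W <- tags[["256"]]
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, tags[["273"]])
    vals <- readBin(con, "double", n = H * W, size = 4L, endian = "little")
    if (length(vals) < H * W)
      stop("truncated TIFF payload in ", basename(path), call. = FALSE)
    img <- t(matrix(vals, W, H))
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L)
      stop(sprintf("expected a single-channel TIFF, found %d channels",
                   dim(img)[3]), call. = FALSE)
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
  }
  check_flow_values(img)
  img
}

# first-IFD tags of a little-endian TIFF as a named list of scalar values;
# NULL when the file is not a TIFF
read_tiff_tags <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:2], as.raw(c(0x49, 0x49)))) return(NULL)
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, ifd_off)
  n <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  if (length(n) == 0L || n <= 0L || n > 512L) return(NULL)
  tags <- list()
  for (i in seq_len(n)) {
    id <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
    type <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
    count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    raw4 <- readBin(con, "raw", 4L)
    value <- if (count == 1L && type %in% c(3L, 4L)) {
      size <- if (type == 3L) 2L else 4L
      sum(as.integer(raw4[seq_len(size)]) * 256^(seq_len(size) - 1L))
    } else NA_integer_
    tags[[as.character(id)]] <- as.integer(value)
  }
  tags
}

check_flow_values <- function(frame) {
  bad <- sum(!is.finite(frame) | frame <= 0)
  if (bad > 0)
    stop(sprintf("blood-flow frame has %d nonpositive or non-finite pixel(s)",
                 bad), call. = FALSE)
  invisible(frame)
}

#' Write an 8-bit colour PNG
#'
#' @param img H x W x 3 array with values in \[0, 1\].
#' @param path PNG path.
#' @export
write_color_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a simulated cohort to a directory tree
#'
#' Layout: `cohort.json` (configuration and per-patient manifest), the
#' morphable model container under `model/`, then per patient a
#' subdirectory with the blood-flow frames as 32-bit float TIFFs, the
#' ground-truth label image as PNG (codes 0-14), the ground-truth
#' landmarks as text, and optionally one colour PNG.
#'
#' @param cohort an `lsci_cohort`.
#' @param path output directory.
#' @param max_frames cap on frames written per patient (NULL = all).
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, max_frames = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cohort$config), patients = list())
  save_model(cohort$model, file.path(path, "model"))
  for (rec in cohort$patients) {
    pdir <- file.path(path, rec$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    nf <- n_frames(rec$frames)
    if (!is.null(max_frames)) nf <- min(nf, max_frames)
    for (i in seq_len(nf))
      write_flow_frame(flow_frame(rec$frames, i),
                       file.path(pdir, sprintf("blood_%03d.tif", i)))
    write_label_png(rec$labels_true, file.path(pdir, "labels_true.png"))
    write_landmarks(rec$landmarks_true, file.path(pdir, "landmarks_true.txt"))
    if (!is.null(rec$color))
      write_color_png(rec$color, file.path(pdir, "color.png"))
    manifest$patients[[rec$patient_id]] <-
      list(hb_grade = rec$hb_grade, ill_side = rec$ill_side,
           n_frames = nf, seed = rec$seed)
  }
  jsonlite::write_json(manifest, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
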