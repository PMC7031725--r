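#' 68-point 2D facial landmarks
#'
#' A 68 x 2 matrix of pixel coordinates (x rightward, y downward, 0-based
#' pixel grid) in iBUG 68-point ordering. Produced by an external landmark
#' detector, by [read_landmarks()], or synthesised from a posed model by
#' [synthesize_landmarks()].
#'
#' @param points numeric 68 x 2 matrix (columns x, y).
#' @return An object of class `landmarks2d`.
#' @export
landmarks2d <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("landmarks must have two columns (x, y)", call. = FALSE)
  if (nrow(points) != 68L)
    stop(sprintf("expected 68 landmark points, found %d", nrow(points)),
         call. = FALSE)
  if (any(!is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("landmarks2d", "matrix"))
}

#' Read / write a 68-point landmark file
#'
#' Two dialects are supported: plain text with one `x y` pair per line
#' (a pts-style header `version:`/`n_points:`/`{`/`}` is tolerated on
#' read), and CSV with an `x,y` header. Coordinates are written with six
#' decimals.
#'
#' @param path file to read or write.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @param lms a `landmarks2d` object (for writing).
#' @return `read_landmarks` returns a `landmarks2d`.
#' @export
read_landmarks <- function(path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop("landmark CSV must have 'x' and 'y' columns", call. = FALSE)
    pts <- cbind(df$x, df$y)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    lines <- lines[!grepl("^(version:|n_points:|\\{|\\})", lines)]
    pts <- matrix(scan(text = lines, quiet = TRUE), ncol = 2L, byrow = TRUE)
  }
  landmarks2d(pts)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lms, path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  lms <- landmarks2d(unclass(lms))
  if (format == "csv") {
    utils::write.csv(
      data.frame(x = sprintf("%.6f", lms[, 1]), y = sprintf("%.6f", lms[, 2])),
      path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(sprintf("%.6f %.6f", lms[, 1], lms[, 2]), path)
  }
  invisible(path)
}

#' Synthesise landmarks from a posed morphable model
#'
#' Projects the model's 68 landmark-correspondence vertices of the
#' instantiated shape through an affine camera and optionally perturbs
#' them with isotropic Gaussian pixel noise. This stands in for an
#' external landmark detector when working with simulated data.
#'
#' @param model a `morphable_model`.
#' @param coeffs shape coefficients (see [instantiate_shape()]).
#' @param camera an `affine_camera`.
#' @param noise_sd nonnegative noise standard deviation in pixels.
#' @param seed optional integer seed; the result is reproducible given
#'   the same seed.
#' @return A `landmarks2d`.
#' @export
synthesize_landmarks <- function(model, coeffs, camera, noise_sd = 0,
                                 seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  mesh <- instantiate_shape(model, coeffs)
  pts <- project(camera, mesh$vertices[model$landmark_corr, , drop = FALSE])
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old))
      set.seed(seed)
    }
    pts <- pts + matrix(stats::rnorm(136L, sd = noise_sd), ncol = 2L)
  }
  landmarks2d(pts)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run code under a temporary seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  code
}
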