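#' Premarked facial region table
#'
#' The seven regions of interest marked on the face model, indexed 1-7.
#' Each region exists on both facial sides (L, left; R, right), giving 14
#' region/side pairs in total. In label images the left-side regions carry
#' codes 1-7 (the region index) and right-side regions codes 8-14
#' (index + 7).
#'
#' @format A data frame with columns `index`, `abbrev` and `name`:
#' eyebrow (B), eye circumference (E), nose wing (N), cheek (C),
#' mouth upper (MU), mouth corner (MC) and mouth below (MB).
#' @export
face_regions <- data.frame(
  index  = 1:7,
  abbrev = c("B", "E", "N", "C", "MU", "MC", "MB"),
  name   = c("eyebrow", "eye circumference", "nose wing", "cheek",
             "mouth upper", "mouth corner", "mouth below"),
  stringsAsFactors = FALSE
)

region_key <- function(region_code, side) paste0(region_code, side)

#' Construct a PCA morphable face shape model
#'
#' A statistical shape model of the face: a mean shape, a matrix of
#' principal deformation modes, their standard deviations, a triangulation,
#' the 68-landmark vertex correspondence, and an atlas mapping each of the
#' 14 premarked (region, side) pairs to a set of model vertices.
#'
#' @param mean_shape numeric N x 3 matrix of mean vertex coordinates.
#' @param basis numeric 3N x M matrix; column i is the (unscaled) i-th
#'   principal component, flattened vertex-major (x1, y1, z1, x2, ...).
#' @param stddevs length-M vector of strictly positive mode standard
#'   deviations; fitting always uses the scaled basis (columns
#'   `stddevs[i] * basis[, i]`) so shape coefficients are standardized.
#' @param triangles integer T x 3 matrix of 1-based vertex indices.
#' @param landmark_corr integer vector of 68 1-based vertex indices giving
#'   the model vertex corresponding to each 2D landmark (iBUG ordering).
#' @param region_atlas named list of integer vertex-index vectors; names
#'   are `paste0(region_code, side)` for region codes 1-7 and sides
#'   `"L"`/`"R"` (e.g. `"2L"` is the left eye circumference).
#' @return An object of class `morphable_model`.
#' @export
morphable_model <- function(mean_shape, basis, stddevs, triangles,
                            landmark_corr, region_atlas) {
  mean_shape <- as.matrix(mean_shape)
  dimnames(mean_shape) <- NULL
  basis <- as.matrix(basis)
  dimnames(basis) <- NULL
  storage.mode(triangles) <- "integer"
  landmark_corr <- as.integer(landmark_corr)
  model <- structure(
    list(mean_shape = mean_shape, basis = basis, stddevs = as.numeric(stddevs),
         triangles = triangles, landmark_corr = landmark_corr,
         region_atlas = lapply(region_atlas, as.integer)),
    class = "morphable_model")
  validate_morphable_model(model)
  model
}

#' Number of vertices / components of a morphable model
#' @param model a `morphable_model`.
#' @return integer count.
#' @export
n_vertices <- function(model) nrow(model$mean_shape)

#' @rdname n_vertices
#' @export
n_components <- function(model) length(model$stddevs)

validate_morphable_model <- function(model) {
  N <- nrow(model$mean_shape)
  M <- length(model$stddevs)
  if (ncol(model$mean_shape) != 3L)
    stop("mean_shape must be N x 3", call. = FALSE)
  if (nrow(model$basis) != 3L * N)
    stop(sprintf("basis has %d rows, expected 3N = %d", nrow(model$basis), 3L * N),
         call. = FALSE)
  if (ncol(model$basis) != M)
    stop(sprintf("basis has %d columns but %d stddevs were given",
                 ncol(model$basis), M), call. = FALSE)
  if (any(!is.finite(model$stddevs)) || any(model$stddevs <= 0))
    stop("stddevs must be finite and strictly positive", call. = FALSE)
  if (ncol(model$triangles) != 3L)
    stop("triangles must be T x 3", call. = FALSE)
  if (any(model$triangles < 1L) || any(model$triangles > N))
    stop("triangle vertex index out of range", call. = FALSE)
  if (length(model$landmark_corr) != 68L)
    stop(sprintf("landmark correspondence must have 68 entries, found %d",
                 length(model$landmark_corr)), call. = FALSE)
  if (any(model$landmark_corr < 1L) || any(model$landmark_corr > N))
    stop("landmark correspondence index out of range", call. = FALSE)
  keys <- as.vector(outer(1:7, c("L", "R"), region_key))
  missing <- setdiff(keys, names(model$region_atlas))
  if (length(missing))
    stop("region atlas is missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  all_idx <- unlist(model$region_atlas[keys], use.names = FALSE)
  if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > N)))
    stop("region atlas vertex index out of range", call. = FALSE)
  if (anyDuplicated(all_idx))
    stop("region atlas vertex sets are not pairwise disjoint", call. = FALSE)
  invisible(model)
}

#' Instantiate a face shape from PCA coefficients
#'
#' Reconstructs vertex positions as the mean shape plus the coefficient-
#' weighted, standard-deviation-scaled principal components:
#' `S = mean + sum_i alpha_i * sigma_i * v_i`. Coefficients are
#' standardized, so `alpha = 0` returns the mean shape exactly.
#'
#' @param model a `morphable_model`.
#' @param coeffs numeric vector of shape coefficients, length at most the
#'   number of model components; shorter vectors are padded with zeros.
#' @return A `face_mesh`: list with `vertices` (N x 3) and `triangles`.
#' @export
instantiate_shape <- function(model, coeffs) {
  coeffs <- as.numeric(coeffs)
  M <- n_components(model)
  if (length(coeffs) > M)
    stop(sprintf("%d coefficients given but the model has only %d components",
                 length(coeffs), M), call. = FALSE)
  if (any(!is.finite(coeffs)))
    stop("shape coefficients must be finite", call. = FALSE)
  verts <- model$mean_shape
  if (length(coeffs) && any(coeffs != 0)) {
    w <- coeffs * model$stddevs[seq_along(coeffs)]
    disp <- model$basis[, seq_along(coeffs), drop = FALSE] %*% w
    verts <- verts + matrix(disp, ncol = 3L, byrow = TRUE)
  }
  structure(list(vertices = verts, triangles = model$triangles),
            class = "face_mesh")
}

#' Vertex set of a premarked facial region
#'
#' @param model a `morphable_model`.
#' @param region_code integer region index 1-7 (see [face_regions]).
#' @param side `"L"` or `"R"`.
#' @return Integer vector of 1-based model vertex indices; always nonempty
#'   for a valid model.
#' @export
region_vertices <- function(model, region_code, side = c("L", "R")) {
  side <- match.arg(side)
  if (!is.numeric(region_code) || length(region_code) != 1L ||
      !(region_code %in% 1:7))
    stop("region_code must be a single integer in 1..7", call. = FALSE)
  model$region_atlas[[region_key(as.integer(region_code), side)]]
}

#' Label-image code of a (region, side) pair
#'
#' Left-side regions map to codes 1-7 (their region index), right-side
#' regions to 8-14 (index + 7); 0 is background.
#' @param region_code integer region index 1-7.
#' @param side `"L"` or `"R"`.
#' @return Integer code in 1..14.
#' @export
region_label_code <- function(region_code, side = c("L", "R")) {
  side <- match.arg(side)
  as.integer(region_code) + if (side == "R") 7L else 0L
}

# flattened (vertex-major) mean shape, used throughout fitting
flatten_vertices <- function(v) as.vector(t(v))

#' Save / load a morphable model container
#'
#' The on-disk container is a directory holding a JSON manifest
#' (`manifest.json` with counts, the region atlas and the landmark
#' correspondences, both 0-based on disk), the mean mesh as ASCII PLY
#' (`mean.ply`), and the PCA arrays as flat little-endian 64-bit float
#' binaries (`basis.f64` column-major, `stddevs.f64`). A save/load round
#' trip reproduces every field bit-exactly.
#'
#' @param model a `morphable_model`.
#' @param path directory to write (created if absent) / read.
#' @return `load_model` returns the `morphable_model`; `save_model`
#'   invisibly returns `path`.
#' @export
save_model <- function(model, path) {
  validate_morphable_model(model)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "flowgrade-morphable-model",
    version = 1L,
    n_vertices = n_vertices(model),
    n_components = n_components(model),
    n_triangles = nrow(model$triangles),
    landmark_corr = model$landmark_corr - 1L,
    region_atlas = lapply(model$region_atlas, function(ix) ix - 1L))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_ply(model$mean_shape, model$triangles, file.path(path, "mean.ply"))
  write_f64(as.vector(model$basis), file.path(path, "basis.f64"))
  write_f64(model$stddevs, file.path(path, "stddevs.f64"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a model container (no manifest.json): ", path, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("n_vertices", "n_components", "n_triangles",
                  "landmark_corr", "region_atlas"))
    if (is.null(mf[[field]]))
      stop("model manifest is missing field '", field, "'", call. = FALSE)
  N <- as.integer(mf$n_vertices); M <- as.integer(mf$n_components)
  mesh <- read_ply(file.path(path, "mean.ply"))
  if (nrow(mesh$vertices) != N)
    stop(sprintf("manifest declares %d vertices but mean.ply has %d",
                 N, nrow(mesh$vertices)), call. = FALSE)
  if (nrow(mesh$triangles) != as.integer(mf$n_triangles))
    stop("manifest triangle count disagrees with mean.ply", call. = FALSE)
  basis_vec <- read_f64(file.path(path, "basis.f64"))
  if (length(basis_vec) != 3L * N * M)
    stop(sprintf(
      "basis.f64 holds %d values, expected 3*N*M = %d (field 'basis')",
      length(basis_vec), 3L * N * M), call. = FALSE)
  sd_vec <- read_f64(file.path(path, "stddevs.f64"))
  if (length(sd_vec) != M)
    stop(sprintf("stddevs.f64 holds %d values, expected M = %d (field 'stddevs')",
                 length(sd_vec), M), call. = FALSE)
  morphable_model(
    mean_shape = mesh$vertices,
    basis = matrix(basis_vec, nrow = 3L * N, ncol = M),
    stddevs = sd_vec,
    triangles = mesh$triangles,
    landmark_corr = as.integer(mf$landmark_corr) + 1L,
    region_atlas = lapply(mf$region_atlas, function(ix) as.integer(ix) + 1L))
}

write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

read_f64 <- function(path) {
  if (!file.exists(path)) stop("missing array file: ", path, call. = FALSE)
  n_bytes <- file.size(path)
  if (n_bytes %% 8L != 0L)
    stop("truncated binary payload in ", basename(path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n_bytes / 8L, size = 8L, endian = "little")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat(sprintf("Morphable face model: %d vertices, %d components, %d triangles\n",
              n_vertices(x), n_components(x), nrow(x$triangles)))
  cat(sprintf("  68 landmark correspondences; 14-region atlas (%d vertices marked)\n",
              length(unlist(x$region_atlas, use.names = FALSE))))
  invisible(x)
}
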