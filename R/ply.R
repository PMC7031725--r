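# Minimal ASCII PLY mesh I/O (vertex x/y/z + triangular faces), enough to
# carry the model's mean mesh. Coordinates are written with full double
# precision (17 significant digits) so round trips are bit-exact.

write_ply <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("element vertex %d", nrow(vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(triangles)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     triangles[, 1] - 1L, triangles[, 2] - 1L,
                     triangles[, 3] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  if (!file.exists(path)) stop("missing mesh file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  if (!grepl("^format ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  header_end <- match("end_header", lines)
  if (is.na(header_end)) stop("PLY header not terminated", call. = FALSE)
  header <- lines[seq_len(header_end)]
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", header, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L)
    stop("PLY header must declare one vertex and one face element", call. = FALSE)
  body <- lines[-seq_len(header_end)]
  if (length(body) < nv + nf) stop("truncated PLY body", call. = FALSE)
  vtx <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), ncol = 3L, byrow = TRUE)
  face_fields <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE),
                        ncol = 4L, byrow = TRUE)
  if (any(face_fields[, 1] != 3))
    stop("non-triangular face in PLY", call. = FALSE)
  tri <- matrix(as.integer(face_fields[, 2:4]) + 1L, ncol = 3L)
  list(vertices = vtx, triangles = tri)
}
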