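#' Project the premarked model regions into a pixel label image
#'
#' For each of the 14 (region, side) pairs, the triangles whose three
#' vertices all belong to the region's vertex set are projected through
#' the fitted camera and rasterised as filled triangles into an H x W
#' label image (codes: 0 background, 1-7 left-side regions, 8-14
#' right-side). Pixels falling outside the image are clipped. With
#' `zbuffer = TRUE`, overlapping projected regions are resolved
#' nearest-first using the camera's depth axis at triangle-centroid
#' granularity; near-frontal acquisition makes self-occlusion of the
#' regions negligible, so the default is off.
#'
#' @param model a `morphable_model`.
#' @param coeffs fitted shape coefficients.
#' @param camera fitted `affine_camera`.
#' @param image_shape integer c(H, W).
#' @param zbuffer logical; resolve region overlap by depth.
#' @return A `region_mask_set`: list with `label` (H x W integer matrix),
#'   `counts` (named per-code pixel counts, codes "1".."14") and `shape`.
#' @export
project_region_masks <- function(model, coeffs, camera, image_shape,
                                 zbuffer = FALSE) {
  if (!inherits(camera, "affine_camera"))
    stop("camera must be an affine_camera (unfitted input?)", call. = FALSE)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0L))
    stop("image_shape must be positive c(H, W)", call. = FALSE)
  H <- image_shape[1]; W <- image_shape[2]
  mesh <- instantiate_shape(model, coeffs)
  p2 <- project(camera, mesh$vertices)
  tri_all <- NULL; code_all <- NULL
  for (side in c("L", "R")) {
    for (rc in 1:7) {
      vset <- region_vertices(model, rc, side)
      in_set <- matrix(model$triangles %in% vset, ncol = 3L)
      tri_r <- model$triangles[rowSums(in_set) == 3L, , drop = FALSE]
      tri_all <- rbind(tri_all, tri_r)
      code_all <- c(code_all, rep.int(region_label_code(rc, side), nrow(tri_r)))
    }
  }
  depth <- NULL
  if (zbuffer && nrow(tri_all)) {
    # view axis = cross product of the camera's two linear rows
    r1 <- camera$C[1, 1:3]; r2 <- camera$C[2, 1:3]
    axis <- c(r1[2] * r2[3] - r1[3] * r2[2],
              r1[3] * r2[1] - r1[1] * r2[3],
              r1[1] * r2[2] - r1[2] * r2[1])
    centroid <- (mesh$vertices[tri_all[, 1], ] + mesh$vertices[tri_all[, 2], ] +
                 mesh$vertices[tri_all[, 3], ]) / 3
    depth <- as.vector(centroid %*% axis)
  }
  lab <- rasterize_label(p2[, 1], p2[, 2], tri_all, code_all, H, W,
                         depth = depth, zbuffer = zbuffer)
  counts <- tabulate(lab[lab > 0L], nbins = 14L)
  names(counts) <- as.character(1:14)
  if (all(counts == 0L))
    warning("all projected region masks are empty (face outside image?)")
  else if (any(counts == 0L))
    warning("empty projected region mask(s): code ",
            paste(which(counts == 0L), collapse = ", "))
  structure(list(label = lab, counts = counts, shape = c(H, W)),
            class = "region_mask_set")
}

#' Dice similarity coefficient of two masks
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)`, the standard overlap agreement between
#' two pixel sets. When both masks are empty the coefficient is defined
#' as 1 (absence agreed in both); empty versus nonempty gives 0.
#'
#' @param mask_x,mask_y logical matrices of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(mask_x, mask_y) {
  if (!identical(dim(mask_x), dim(mask_y)))
    stop("masks must share shape", call. = FALSE)
  nx <- sum(mask_x); ny <- sum(mask_y)
  if (nx + ny == 0) return(1)
  2 * sum(mask_x & mask_y) / (nx + ny)
}

#' Per-region and pooled Dice of two label images
#'
#' Computes the Dice coefficient for each of the 14 region codes and the
#' pooled multi-region value
#' `2 * sum_i |X_i n Y_i| / sum_i (|X_i| + |Y_i|)` — the overlap pooled
#' over regions before division, not the mean of per-region values.
#'
#' @param set_x,set_y `region_mask_set` objects (or plain integer label
#'   matrices with codes 0-14) of identical shape.
#' @return A `dsc_report`: list with `per_region` (data frame: code,
#'   region, side, dsc) and `combined` (pooled scalar).
#' @export
multi_region_dsc <- function(set_x, set_y) {
  lx <- if (inherits(set_x, "region_mask_set")) set_x$label else set_x
  ly <- if (inherits(set_y, "region_mask_set")) set_y$label else set_y
  if (!identical(dim(lx), dim(ly)))
    stop("label images must share shape", call. = FALSE)
  inter <- numeric(14); size_sum <- numeric(14); per <- numeric(14)
  for (code in 1:14) {
    mx <- lx == code; my <- ly == code
    inter[code] <- sum(mx & my)
    size_sum[code] <- sum(mx) + sum(my)
    per[code] <- if (size_sum[code] == 0) 1 else 2 * inter[code] / size_sum[code]
  }
  combined <- if (sum(size_sum) == 0) 1 else 2 * sum(inter) / sum(size_sum)
  report <- data.frame(
    code = 1:14,
    region = face_regions$abbrev[c(1:7, 1:7)],
    side = rep(c("L", "R"), each = 7L),
    dsc = per,
    stringsAsFactors = FALSE)
  structure(list(per_region = report, combined = combined),
            class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  cat("Per-region Dice similarity:\n")
  print(x$per_region, row.names = FALSE)
  cat(sprintf("Pooled multi-region DSC: %.4f\n", x$combined))
  invisible(x)
}

#' Write / read a label image as 8-bit PNG (codes 0-14)
#'
#' @param masks a `region_mask_set` or integer label matrix.
#' @param path PNG path.
#' @return `read_label_png` returns an integer label matrix.
#' @export
write_label_png <- function(masks, path) {
  lab <- if (inherits(masks, "region_mask_set")) masks$label else masks
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  if (any(lab > 14L))
    stop("label PNG contains codes above 14", call. = FALSE)
  lab
}
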