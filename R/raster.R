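# Triangle rasterization on the 0-based pixel grid.
#
# Convention: image domain [0, W) x [0, H), pixel centres at integer
# coordinates (x, y), x rightward and y downward; images are stored as
# H x W matrices indexed [y + 1, x + 1]. A pixel centre lying exactly on
# a shared edge is assigned to exactly one of the two triangles by a
# deterministic top-left-style rule, so meshes rasterise without double
# coverage or cracks.

edge_fun <- function(ax, ay, bx, by, px, py) {
  (bx - ax) * (py - ay) - (by - ay) * (px - ax)
}

# include a zero-area-weight pixel iff its edge is a "top-left" edge
edge_accept <- function(dx, dy) (dy > 0) | (dy == 0 & dx < 0)

# Rasterise triangles; returns pixel linear indices (column-major into an
# H x W matrix), triangle ids and normalised barycentric weights.
rasterize_barycentric <- function(px, py, tri, H, W) {
  out_pix <- vector("list", nrow(tri)); out_tri <- out_pix
  out_w1 <- out_pix; out_w2 <- out_pix; out_w3 <- out_pix
  for (t in seq_len(nrow(tri))) {
    i1 <- tri[t, 1]; i2 <- tri[t, 2]; i3 <- tri[t, 3]
    x1 <- px[i1]; y1 <- py[i1]; x2 <- px[i2]; y2 <- py[i2]
    x3 <- px[i3]; y3 <- py[i3]
    area2 <- edge_fun(x1, y1, x2, y2, x3, y3)
    if (area2 == 0) next
    if (area2 < 0) {  # reorient positively; weights follow the swap
      tmp <- x2; x2 <- x3; x3 <- tmp
      tmp <- y2; y2 <- y3; y3 <- tmp
      tmp <- i2; i2 <- i3; i3 <- tmp
      area2 <- -area2
    }
    xlo <- max(0L, as.integer(ceiling(min(x1, x2, x3))))
    xhi <- min(W - 1L, as.integer(floor(max(x1, x2, x3))))
    ylo <- max(0L, as.integer(ceiling(min(y1, y2, y3))))
    yhi <- min(H - 1L, as.integer(floor(max(y1, y2, y3))))
    if (xlo > xhi || ylo > yhi) next
    gx <- rep(xlo:xhi, each = yhi - ylo + 1L)
    gy <- rep(ylo:yhi, times = xhi - xlo + 1L)
    w1 <- edge_fun(x2, y2, x3, y3, gx, gy)
    w2 <- edge_fun(x3, y3, x1, y1, gx, gy)
    w3 <- edge_fun(x1, y1, x2, y2, gx, gy)
    keep <- (w1 > 0 | (w1 == 0 & edge_accept(x3 - x2, y3 - y2))) &
            (w2 > 0 | (w2 == 0 & edge_accept(x1 - x3, y1 - y3))) &
            (w3 > 0 | (w3 == 0 & edge_accept(x2 - x1, y2 - y1)))
    if (!any(keep)) next
    out_pix[[t]] <- gx[keep] * H + gy[keep] + 1L
    out_tri[[t]] <- rep.int(t, sum(keep))
    out_w1[[t]] <- w1[keep] / area2
    out_w2[[t]] <- w2[keep] / area2
    out_w3[[t]] <- w3[keep] / area2
  }
  res <- list(pix = unlist(out_pix, use.names = FALSE),
              tri = unlist(out_tri, use.names = FALSE),
              w1 = unlist(out_w1, use.names = FALSE),
              w2 = unlist(out_w2, use.names = FALSE),
              w3 = unlist(out_w3, use.names = FALSE))
  # weights w1..w3 correspond to the (possibly swapped) vertex order; we
  # recompute the vertex ids per hit from the original triangle rows,
  # honouring the swap applied when area2 was negative.
  area2_all <- edge_fun(px[tri[, 1]], py[tri[, 1]], px[tri[, 2]], py[tri[, 2]],
                        px[tri[, 3]], py[tri[, 3]])
  swapped <- area2_all < 0
  v1 <- tri[res$tri, 1]
  v2 <- ifelse(swapped[res$tri], tri[res$tri, 3], tri[res$tri, 2])
  v3 <- ifelse(swapped[res$tri], tri[res$tri, 2], tri[res$tri, 3])
  res$v1 <- v1; res$v2 <- v2; res$v3 <- v3
  res
}

# Sparse (H*W) x N matrix mapping per-vertex values to covered pixels by
# barycentric interpolation; duplicate pixel coverage keeps the first hit.
pixel_vertex_map <- function(px, py, tri, H, W, n_vertices) {
  hit <- rasterize_barycentric(px, py, tri, H, W)
  if (length(hit$pix) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(H * W, n_vertices)))
  first <- !duplicated(hit$pix)
  Matrix::sparseMatrix(
    i = rep(hit$pix[first], 3L),
    j = c(hit$v1[first], hit$v2[first], hit$v3[first]),
    x = c(hit$w1[first], hit$w2[first], hit$w3[first]),
    dims = c(H * W, n_vertices))
}

# Label image from coded triangles. With zbuffer, per-triangle depths
# resolve overlaps nearest-first; otherwise triangles are painted in the
# order given.
rasterize_label <- function(px, py, tri, codes, H, W,
                            depth = NULL, zbuffer = FALSE) {
  lab <- matrix(0L, H, W)
  if (nrow(tri) == 0L) return(lab)
  hit <- rasterize_barycentric(px, py, tri, H, W)
  if (length(hit$pix) == 0L) return(lab)
  if (zbuffer && !is.null(depth)) {
    # paint far-to-near so nearer triangles overwrite
    ord <- order(depth[hit$tri])
    lab[hit$pix[ord]] <- codes[hit$tri[ord]]
  } else {
    lab[hit$pix] <- codes[hit$tri]
  }
  lab
}

# isotropic Gaussian blur of an H x W matrix (EBImage, FFT-based)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

# w x w box mean filter
box_mean <- function(img, w) {
  as.matrix(EBImage::filter2(img, matrix(1 / (w * w), w, w)))
}
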