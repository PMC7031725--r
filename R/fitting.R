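#' Affine camera
#'
#' A 3 x 4 projection matrix mapping homogeneous 3D model points to
#' homogeneous 2D pixel points. The last row is constrained to
#' (0, 0, 0, 1), i.e. parallel projection composed with an affine image
#' transform; the third homogeneous output coordinate is therefore
#' always 1.
#'
#' @param C numeric 3 x 4 matrix with last row (0, 0, 0, 1).
#' @return An object of class `affine_camera`.
#' @export
affine_camera <- function(C) {
  C <- as.matrix(C)
  dimnames(C) <- NULL
  if (!all(dim(C) == c(3L, 4L)))
    stop("camera matrix must be 3 x 4", call. = FALSE)
  if (any(!is.finite(C)))
    stop("camera matrix must be finite", call. = FALSE)
  if (!identical(as.numeric(C[3, ]), c(0, 0, 0, 1)))
    stop("affine camera requires last row (0, 0, 0, 1)", call. = FALSE)
  structure(list(C = C), class = "affine_camera")
}

#' Fitting configuration
#'
#' @param sigma_2d positive landmark noise scale in pixels; the shape
#'   solve is a ridge problem with penalty `2 * sigma_2d^2` on the
#'   standardized coefficients, so larger values shrink the fit towards
#'   the mean face. Default 3 px, a typical detector error.
#' @param iterations number of camera/shape alternations (>= 1). With 1,
#'   the camera is estimated once against the mean-shape correspondences
#'   and the shape solved once; larger values re-estimate the camera
#'   against the current fitted mesh and re-solve.
#' @return A `fit_config` list.
#' @export
fit_config <- function(sigma_2d = 3, iterations = 1L) {
  if (!is.numeric(sigma_2d) || sigma_2d <= 0)
    stop("sigma_2d must be > 0", call. = FALSE)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be >= 1", call. = FALSE)
  structure(list(sigma_2d = sigma_2d, iterations = iterations),
            class = "fit_config")
}

#' Project 3D points through an affine camera
#'
#' Computes `p = C %*% c(v, 1)` for each vertex and dehomogenises; with an
#' affine camera the homogeneous divisor is exactly 1.
#'
#' @param camera an `affine_camera`.
#' @param vertices numeric n x 3 matrix.
#' @return n x 2 matrix of pixel coordinates (x, y).
#' @export
project <- function(camera, vertices) {
  vertices <- as.matrix(vertices)
  if (is.null(dim(vertices))) vertices <- matrix(vertices, ncol = 3L)
  if (any(!is.finite(vertices)))
    stop("vertices must be finite", call. = FALSE)
  A <- camera$C[1:2, 1:3, drop = FALSE]
  t2 <- camera$C[1:2, 4]
  sweep(vertices %*% t(A), 2L, -t2)
}

#' Estimate an affine camera from 2D-3D correspondences
#'
#' The gold-standard algorithm for the affine camera: both point sets are
#' translated to zero centroid and isotropically scaled (2D to RMS
#' distance sqrt(2), 3D to sqrt(3)) for conditioning, the two rows of the
#' affine map are solved by least squares, and the result is denormalised
#' back to pixel units. The returned camera minimises the total squared
#' reprojection error over all affine 3 x 4 matrices.
#'
#' @param points2d n x 2 pixel coordinates (n >= 4).
#' @param points3d n x 3 model coordinates; must not be coplanar.
#' @return An `affine_camera`.
#' @export
estimate_affine_camera <- function(points2d, points3d) {
  points2d <- as.matrix(points2d); points3d <- as.matrix(points3d)
  if (nrow(points2d) != nrow(points3d))
    stop(sprintf("correspondence count mismatch: %d 2D vs %d 3D points",
                 nrow(points2d), nrow(points3d)), call. = FALSE)
  n <- nrow(points2d)
  if (n < 4L)
    stop("at least 4 correspondences are required", call. = FALSE)
  # normalization: zero centroid, isotropic RMS scale sqrt(d)
  c2 <- colMeans(points2d); c3 <- colMeans(points3d)
  q2 <- sweep(points2d, 2L, c2); q3 <- sweep(points3d, 2L, c3)
  s2 <- sqrt(2 / mean(rowSums(q2^2)))
  s3 <- sqrt(3 / mean(rowSums(q3^2)))
  sv <- svd(q3, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * sv[1])
    stop("degenerate 3D configuration: correspondence points are coplanar",
         call. = FALSE)
  q2 <- q2 * s2; q3 <- q3 * s3
  # two independent least-squares rows in normalized frames
  X <- cbind(q3, 1)
  Ahat <- qr.solve(X, q2)            # 4 x 2
  Cn <- rbind(t(Ahat), c(0, 0, 0, 1))
  # denormalize: C = T2^-1 %*% Cn %*% T3
  T3 <- rbind(cbind(diag(3) * s3, -s3 * c3), c(0, 0, 0, 1))
  T2inv <- rbind(cbind(diag(2) / s2, c2), c(0, 0, 1))
  C <- T2inv %*% Cn %*% T3
  C[3, ] <- c(0, 0, 0, 1)            # exact affine row
  affine_camera(C)
}

# projection matrix rows of the scaled basis restricted to the 68
# correspondence vertices: returns list(A = 136 x M, b0 = projected mean)
landmark_design <- function(model, camera, n_coeffs = n_components(model)) {
  corr <- model$landmark_corr
  M <- n_coeffs
  A2 <- camera$C[1:2, 1:3, drop = FALSE]
  rows <- as.vector(rbind(3L * (corr - 1L) + 1L,
                          3L * (corr - 1L) + 2L,
                          3L * (corr - 1L) + 3L))
  B <- model$basis[rows, seq_len(M), drop = FALSE] *
    rep(model$stddevs[seq_len(M)], each = length(rows))
  # apply the camera's 2x3 linear part blockwise over the 68 vertices
  A <- matrix(0, nrow = 136L, ncol = M)
  for (j in seq_len(M)) {
    V <- matrix(B[, j], ncol = 3L, byrow = TRUE)   # 68 x 3
    A[, j] <- as.vector(t(V %*% t(A2)))            # x1,y1,x2,y2,...
  }
  mean_proj <- project(camera, model$mean_shape[corr, , drop = FALSE])
  list(A = A, mean_proj = mean_proj)
}

#' Solve the shape coefficients for a fixed camera
#'
#' Minimises the regularised landmark reprojection cost
#' `E = sum_i ||y_i - x_i||^2 / (2 sigma_2d^2) + ||alpha||^2`, where `y_i`
#' is the camera projection of correspondence vertex i of the
#' instantiated shape and `x_i` the observed landmark. Because the model
#' is linear in the standardized coefficients the minimiser is the
#' closed-form ridge solution of
#' `(A'A + 2 sigma_2d^2 I) alpha = A'b`.
#'
#' @param model a `morphable_model`.
#' @param camera an `affine_camera`.
#' @param landmarks a `landmarks2d`.
#' @param config a [fit_config()].
#' @param n_coeffs number of leading components to solve for (default all).
#' @return Numeric coefficient vector with attribute `"condition"`, the
#'   2-norm condition number of the regularised normal matrix.
#' @export
fit_shape <- function(model, camera, landmarks, config = fit_config(),
                      n_coeffs = n_components(model)) {
  landmarks <- landmarks2d(unclass(landmarks))
  if (n_coeffs > n_components(model))
    stop("n_coeffs exceeds the number of model components", call. = FALSE)
  des <- landmark_design(model, camera, n_coeffs)
  b <- as.vector(t(unclass(landmarks) - des$mean_proj))
  lambda <- 2 * config$sigma_2d^2
  G <- crossprod(des$A) + diag(lambda, n_coeffs)
  alpha <- as.vector(solve(G, crossprod(des$A, b)))
  ev <- range(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  structure(alpha, condition = ev[2] / ev[1])
}

# Eq-style cost of a candidate fit (reprojection + coefficient prior)
fit_cost <- function(model, camera, landmarks, alpha, sigma_2d) {
  mesh <- instantiate_shape(model, alpha)
  y <- project(camera, mesh$vertices[model$landmark_corr, , drop = FALSE])
  sum((y - unclass(landmarks))^2) / (2 * sigma_2d^2) + sum(alpha^2)
}

#' Fit camera and shape to observed landmarks
#'
#' Step one estimates the affine camera from the landmarks against the
#' mean-shape correspondence vertices; step two solves the shape
#' coefficients in closed form ([fit_shape()]). With `iterations > 1`
#' the camera is re-estimated against the current fitted mesh and the
#' shape re-solved; the regularised cost is non-increasing across
#' alternations (monitored and returned).
#'
#' @inheritParams fit_shape
#' @return A list of class `face_fit`: `camera`, `coeffs`, `cost` (trace
#'   over alternations), `rmse` (final landmark reprojection RMSE, px).
#' @export
fit_face <- function(model, landmarks, config = fit_config(),
                     n_coeffs = n_components(model)) {
  landmarks <- landmarks2d(unclass(landmarks))
  corr <- model$landmark_corr
  pts3d <- model$mean_shape[corr, , drop = FALSE]
  camera <- estimate_affine_camera(unclass(landmarks), pts3d)
  alpha <- fit_shape(model, camera, landmarks, config, n_coeffs)
  cost <- fit_cost(model, camera, landmarks, alpha, config$sigma_2d)
  if (config$iterations > 1L) {
    for (it in 2:config$iterations) {
      mesh <- instantiate_shape(model, alpha)
      cam_new <- estimate_affine_camera(unclass(landmarks),
                                        mesh$vertices[corr, , drop = FALSE])
      alpha_new <- fit_shape(model, cam_new, landmarks, config, n_coeffs)
      cost_new <- fit_cost(model, cam_new, landmarks, alpha_new, config$sigma_2d)
      if (cost_new > cost[length(cost)] + 1e-9) break  # refuse uphill step
      camera <- cam_new; alpha <- alpha_new
      cost <- c(cost, cost_new)
    }
  }
  mesh <- instantiate_shape(model, alpha)
  y <- project(camera, mesh$vertices[corr, , drop = FALSE])
  rmse <- sqrt(mean(rowSums((y - unclass(landmarks))^2)))
  structure(list(camera = camera, coeffs = as.numeric(alpha),
                 cost = cost, rmse = rmse),
            class = "face_fit")
}

#' Serialise / restore a fit result as JSON
#'
#' @param fit a `face_fit` from [fit_face()].
#' @param path JSON file path.
#' @return `read_fit` returns the `face_fit` (without the cost trace).
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(camera = as.vector(t(fit$camera$C)),  # row-major 3x4
         coeffs = fit$coeffs, rmse = fit$rmse),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(camera = affine_camera(matrix(obj$camera, 3L, 4L, byrow = TRUE)),
                 coeffs = as.numeric(obj$coeffs), cost = NULL,
                 rmse = obj$rmse),
            class = "face_fit")
}

#' @export
print.face_fit <- function(x, ...) {
  cat(sprintf("Face fit: %d coefficients, reprojection RMSE %.4g px\n",
              length(x$coeffs), x$rmse))
  invisible(x)
}
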