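test_that("projection agrees with per-point homogeneous multiplication", {
  set.seed(21)
  cam <- random_affine_camera()
  V <- matrix(rnorm(3000), ncol = 3)
  p <- project(cam, V)
  oracle <- t(apply(V, 1, function(v) (cam$C %*% c(v, 1))[1:2]))
  expect_lt(max(abs(p - oracle)), 1e-12)

  # identity-like orthographic drop-z camera
  ortho <- affine_camera(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 1)))
  expect_equal(project(ortho, V), V[, 1:2], ignore_attr = TRUE)

  # translation-only equivariance
  shifted <- cam$C; shifted[1:2, 4] <- shifted[1:2, 4] + c(3, -7)
  expect_equal(project(affine_camera(shifted), V), sweep(p, 2, c(-3, 7)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gold-standard camera estimation recovers exact affine cameras", {
  set.seed(22)
  V <- matrix(rnorm(68 * 3, sd = 40), ncol = 3)

  # orthographic drop-z observations
  cam <- estimate_affine_camera(V[, 1:2], V)
  expect_lt(sqrt(mean(rowSums((project(cam, V) - V[, 1:2])^2))), 1e-9)

  # random affine ground-truth cameras, noiseless: RMSE < 1e-8 px
  for (rep in 1:5) {
    C_true <- random_affine_camera()
    obs <- project(C_true, V)
    est <- estimate_affine_camera(obs, V)
    rmse <- sqrt(mean(rowSums((project(est, V) - obs)^2)))
    expect_lt(rmse, 1e-8)
  }
})

test_that("camera estimation rejects degenerate geometry and bad input", {
  set.seed(23)
  flat <- cbind(matrix(rnorm(68 * 2), ncol = 2), 5)  # coplanar z = 5
  obs <- flat[, 1:2]
  expect_error(estimate_affine_camera(obs, flat), "coplanar|degenerate")
  expect_error(estimate_affine_camera(obs[1:10, ], flat), "mismatch")
  expect_error(estimate_affine_camera(obs[1:3, , drop = FALSE],
                                      flat[1:3, , drop = FALSE]), "4")
})

test_that("camera estimation is invariant under 2D similarity transforms", {
  set.seed(24)
  V <- matrix(rnorm(68 * 3, sd = 30), ncol = 3)
  obs <- project(random_affine_camera(), V) +
    matrix(rnorm(136, sd = 0.5), ncol = 2)
  cam1 <- estimate_affine_camera(obs, V)
  th <- 0.7; s <- 2.3; t <- c(40, -15)
  Rm <- s * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  obs2 <- sweep(obs %*% t(Rm), 2, -t)
  cam2 <- estimate_affine_camera(obs2, V)
  # reprojections must transform exactly like the points
  p1 <- sweep(project(cam1, V) %*% t(Rm), 2, -t)
  p2 <- project(cam2, V)
  expect_lt(max(abs(p1 - p2)), 1e-9)
})

test_that("shape solve matches the ridge closed form and its limits", {
  model <- test_model()
  cam <- frontal_camera(128)
  M <- n_components(model)

  # landmarks from the mean shape give exactly zero coefficients
  lms0 <- synthesize_landmarks(model, rep(0, M), cam, noise_sd = 0)
  a0 <- fit_shape(model, cam, lms0)
  expect_identical(max(abs(a0)), 0)

  # huge sigma_2d drives the solution to the prior
  set.seed(31)
  lms <- synthesize_landmarks(model, rnorm(M), cam, noise_sd = 0)
  a_ridge <- fit_shape(model, cam, lms, fit_config(sigma_2d = 1e6))
  expect_lt(sqrt(sum(a_ridge^2)), 1e-6)

  # noiseless parameter recovery vs an independently assembled oracle:
  # project each scaled basis column through the camera by brute force
  alpha_true <- with_seed(77, rnorm(M))
  lms_t <- synthesize_landmarks(model, alpha_true, cam, noise_sd = 0)
  sigma <- 1e-3
  a_hat <- fit_shape(model, cam, lms_t, fit_config(sigma_2d = sigma))
  corr <- model$landmark_corr
  A <- sapply(seq_len(M), function(j) {
    disp <- matrix(model$basis[, j] * model$stddevs[j], ncol = 3, byrow = TRUE)
    one_mode <- project(cam, model$mean_shape + disp) -
      project(cam, model$mean_shape)
    as.vector(t(one_mode[corr, ]))
  })
  b <- as.vector(t(unclass(lms_t) - project(cam, model$mean_shape[corr, ])))
  a_oracle <- solve(crossprod(A) + diag(2 * sigma^2, M), crossprod(A, b))
  expect_lt(max(abs(a_hat - a_oracle)), 1e-9)
  expect_lt(max(abs(a_hat - alpha_true)), 1e-3)
})

test_that("the returned coefficients zero the cost gradient", {
  model <- test_model()
  cam <- frontal_camera(128)
  M <- n_components(model)
  set.seed(41)
  lms <- synthesize_landmarks(model, rnorm(M), cam, noise_sd = 1, seed = 8)
  sigma <- 3
  a_hat <- as.numeric(fit_shape(model, cam, lms, fit_config(sigma_2d = sigma)))
  eps <- 1e-6
  grad <- vapply(seq_len(M), function(j) {
    e <- rep(0, M); e[j] <- eps
    (flowgrade:::fit_cost(model, cam, lms, a_hat + e, sigma) -
       flowgrade:::fit_cost(model, cam, lms, a_hat - e, sigma)) / (2 * eps)
  }, numeric(1))
  expect_lt(sqrt(sum(grad^2)), 1e-5)
})

test_that("full fit recovers pose and shape; alternation never increases cost", {
  model <- test_model()
  M <- n_components(model)
  cam_true <- frontal_camera(256)
  alpha_true <- with_seed(55, rnorm(M))
  lms <- synthesize_landmarks(model, alpha_true, cam_true, noise_sd = 0)

  fit1 <- fit_face(model, lms, fit_config(sigma_2d = 1e-3, iterations = 1))
  expect_lt(fit1$rmse, 1e-6)
  expect_lt(max(abs(fit1$coeffs - alpha_true)), 1e-3)

  # iterations = 1 is exactly the two sub-operations composed by hand
  cam_manual <- estimate_affine_camera(
    unclass(lms), model$mean_shape[model$landmark_corr, ])
  a_manual <- fit_shape(model, cam_manual, lms, fit_config(sigma_2d = 1e-3))
  expect_identical(fit1$coeffs, as.numeric(a_manual))
  expect_identical(fit1$camera$C, cam_manual$C)

  fit3 <- fit_face(model, lms, fit_config(sigma_2d = 1e-3, iterations = 3))
  expect_lt(fit3$rmse, 1e-6)

  # monotone cost audit over noisy landmark sets
  for (sd_i in 1:20) {
    lms_n <- synthesize_landmarks(model, alpha_true, cam_true,
                                  noise_sd = 1.5, seed = sd_i)
    ff <- fit_face(model, lms_n, fit_config(sigma_2d = 3, iterations = 4))
    expect_true(all(diff(ff$cost) <= 1e-9))
  }
})

test_that("recovery error grows smoothly with landmark noise", {
  model <- test_model()
  M <- n_components(model)
  cam <- frontal_camera(256)
  alpha_true <- with_seed(66, rnorm(M))
  err_at <- function(noise, seed) {
    lms <- synthesize_landmarks(model, alpha_true, cam, noise, seed = seed)
    fit <- fit_face(model, lms, fit_config(sigma_2d = max(noise, 1e-3)))
    sqrt(mean((fit$coeffs - alpha_true)^2))
  }
  e0 <- mean(vapply(1:5, function(s) err_at(1e-6, s), numeric(1)))
  e1 <- mean(vapply(1:5, function(s) err_at(1, s), numeric(1)))
  expect_lt(e1, 10 * max(e0, 0.02))
})
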