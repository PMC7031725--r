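test_that("synthetic model construction is deterministic and well formed", {
  m1 <- build_synthetic_model(2500, 5, seed = 42)
  m2 <- build_synthetic_model(2500, 5, seed = 42)
  expect_identical(m1$mean_shape, m2$mean_shape)
  expect_identical(m1$basis, m2$basis)
  expect_identical(m1$landmark_corr, m2$landmark_corr)
  expect_gte(n_vertices(m1), 2500)

  # orthonormal basis columns
  G <- crossprod(m1$basis)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)

  expect_error(build_synthetic_model(200, 5), "300")
  # coarse grids cannot give the thin regions an interior triangle
  expect_error(build_synthetic_model(1200, 5), "interior triangle")
})

test_that("perfusion multiplier encodes the severity trend", {
  expect_equal(as.numeric(perfusion_multiplier(1)), 1)
  m6 <- perfusion_multiplier(6, delta = 0.09)
  expect_equal(as.numeric(m6), 0.55)
  expect_equal(attr(m6, "expected_pr"), 1 / 0.55)
  ms <- as.numeric(perfusion_multiplier(1:6, delta = 0.05))
  expect_true(all(diff(ms) < 0))
  expect_error(perfusion_multiplier(6, delta = 0.25), "positive")
  expect_error(simulation_config(delta = 0.25), "delta")
})

test_that("simulated patients are reproducible and physically valid", {
  cfg <- small_sim_config()
  model <- test_model()
  r1 <- simulate_patient(model, "P1", 4L, cfg, seed = 99L)
  r2 <- simulate_patient(model, "P1", 4L, cfg, seed = 99L)
  expect_identical(unclass(r1$frames)[, ], unclass(r2$frames)[, ])
  expect_identical(r1$ill_side, r2$ill_side)
  expect_identical(r1$coeffs, r2$coeffs)

  # device output contract: strictly positive finite perfusion values
  expect_true(all(is.finite(r1$frames)) && all(r1$frames > 0))
  expect_identical(dim(r1$frames), c(96L * 96L, 12L))
})

test_that("cohort composition follows the configuration", {
  cfg <- small_sim_config()
  co <- simulate_cohort(cfg)
  expect_length(co$patients, 12)
  grades <- vapply(co$patients, `[[`, integer(1), "hb_grade")
  expect_identical(as.integer(table(grades)), rep(2L, 6))
  sides <- vapply(co$patients, `[[`, character(1), "ill_side")
  expect_true(all(sides[grades == 1] == "R"))  # healthy convention
  total_frames <- sum(vapply(co$patients, function(p) n_frames(p$frames),
                             integer(1)))
  expect_identical(total_frames, 12L * 12L)
})

test_that("per-patient seeds are stable under cohort extension", {
  cfg_small <- small_sim_config()
  cfg_big <- small_sim_config()
  cfg_big$participants_per_grade <- c(2L, 2L, 2L, 2L, 2L, 4L)
  model <- test_model()
  a <- simulate_cohort(cfg_small, model = model)
  b <- simulate_cohort(cfg_big, model = model)
  expect_identical(unclass(a$patients[[3]]$frames)[, ],
                   unclass(b$patients[[3]]$frames)[, ])
})

test_that("motion artifacts elevate frames and QC flags exactly them", {
  cfg <- small_sim_config(artifact_fraction = 0)
  model <- test_model()
  rec <- simulate_patient(model, "P1", 2L, cfg, seed = 5L)
  frame <- flow_frame(rec$frames, 1)

  expect_error(inject_motion_artifact(frame, amplitude = 1), "exceed")
  doubled <- inject_motion_artifact(frame, amplitude = 2, blur_sigma = 0)
  expect_equal(mean(doubled), 2 * mean(frame), tolerance = 1e-12)
  blurred <- inject_motion_artifact(frame, amplitude = 2)
  expect_gt(mean(blurred), mean(frame))

  # 95 clean + 5 amplitude-2 artifacts: exactly the 5 are flagged
  cfg100 <- small_sim_config(artifact_fraction = 0, frames_per_patient = 100)
  rec100 <- simulate_patient(model, "P2", 3L, cfg100, seed = 11L)
  stack <- rec100$frames
  hit <- c(7L, 23L, 41L, 68L, 90L)
  for (i in hit)
    stack[, i] <- as.vector(inject_motion_artifact(flow_frame(stack, i), 2))
  qc <- qc_filter(stack)
  expect_identical(qc$flagged, hit)
  expect_identical(n_frames(qc$kept), 95L)

  # clean series: at most a couple of false positives
  qc0 <- qc_filter(rec100$frames)
  expect_lte(length(qc0$flagged), 2)

  # degenerate scale
  const <- flowgrade:::flow_stack(matrix(1, 64, 10), 8, 8)
  expect_warning(qcc <- qc_filter(const), "degenerate")
  expect_length(qcc$flagged, 0)
  expect_error(qc_filter(flowgrade:::flow_stack(matrix(1, 64, 4), 8, 8)), "5")
})

test_that("grade I cohorts are symmetric in expectation", {
  cfg <- simulation_config(image_size = c(32, 32))
  draws <- sample_regional_flux(1, cfg, n = 10000, seed = 21)
  A <- draws$flux[, 8:14]  # ill side R = codes 8-14
  H <- draws$flux[, 1:7]
  expect_lt(max(abs(colMeans(A) / colMeans(H) - 1)), 0.02)
  expect_true(all(draws$ill_side == "R"))
})

test_that("speckle contrast maps flow monotonically and invertibly", {
  # uniform flow: contrast spatially uniform up to sampling noise
  uni <- speckle_forward(matrix(2, 96, 96), window = 7, seed = 3)
  expect_lt(sd(uni$contrast) / mean(uni$contrast), 0.05)

  # two-level map: the high-flow half has strictly lower mean contrast
  two <- matrix(c(rep(1, 48 * 96), rep(6, 48 * 96)), 96, 96)
  res2 <- speckle_forward(two, window = 7, seed = 4)
  expect_lt(mean(res2$contrast[, 49:96]), mean(res2$contrast[, 1:48]))

  # smooth random field: 1/K^2 ranks with true flow
  set.seed(5)
  field <- matrix(rnorm(128 * 128), 128, 128)
  field <- as.matrix(EBImage::gblur(field, sigma = 10))
  flow <- 0.5 + 4 * (field - min(field)) / diff(range(field))
  res <- speckle_forward(flow, window = 7, exposure_scale = 2, seed = 6)
  rc <- cor(as.vector(res$flow_estimate), as.vector(flow), method = "spearman")
  expect_gt(rc, 0.95)

  expect_error(speckle_forward(matrix(-1, 8, 8)), "positive")
  expect_error(speckle_forward(matrix(1, 8, 8), window = 4), "odd")
})
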