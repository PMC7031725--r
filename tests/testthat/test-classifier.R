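# small synthetic feature sets built from the generative flux model
flux_features <- function(grades, config, seed0 = 1000) {
  rows <- lapply(seq_along(grades), function(i) {
    d <- sample_regional_flux(grades[i], config, n = 1, seed = seed0 + i)
    fv <- order_and_normalize(flowgrade:::region_means_from_vector(d$flux[1, ]),
                              d$ill_side[1])
    row <- data.frame(patient_id = sprintf("S%03d", i), ill_side = d$ill_side[1],
                      hb_grade = grades[i], stringsAsFactors = FALSE)
    row[flowgrade:::feature_names()] <- as.list(unclass(fv))
    row
  })
  do.call(rbind, rows)
}

noiseless_config <- function(delta = 0.15)
  simulation_config(image_size = c(32, 32), delta = delta,
                    subject_scale_sd = 0, region_jitter_sd = 0,
                    frame_noise_sd = 0)

test_that("K-NN likelihoods equal brute-force 11-NN vote fractions", {
  set.seed(31)
  X <- matrix(rnorm(30 * 14), 30, 14)
  y <- rep(c(2L, 5L), each = 15)
  clf <- train_hb_classifier(classifier_spec("knn"), X, y)
  Q <- matrix(rnorm(8 * 14), 8, 14)
  lik <- predict_likelihood(clf, Q)
  for (i in 1:8) {
    d <- sqrt(colSums((t(X) - Q[i, ])^2))
    nb <- sort(order(d)[1:11])
    votes <- table(factor(y[nb], levels = 1:6)) / 11
    expect_equal(unname(lik[i, ]), as.numeric(votes), tolerance = 1e-12)
  }
})

test_that("K-NN agrees with the class package on majority votes", {
  skip_if_not_installed("class")
  set.seed(32)
  X <- matrix(rnorm(60 * 14), 60, 14)
  y <- rep(1:3, each = 20)
  Q <- matrix(rnorm(25 * 14), 25, 14)
  clf <- train_hb_classifier(classifier_spec("knn", knn_k = 5), X, y)
  ours <- predict_grade(clf, Q)
  theirs <- as.integer(as.character(class::knn(X, Q, factor(y), k = 5)))
  # compare where the vote is unambiguous (class breaks ties at random)
  lik <- predict_likelihood(clf, Q)
  clear <- apply(lik, 1, function(p) sum(p == max(p)) == 1)
  expect_equal(ours[clear], theirs[clear])
})

test_that("single-class K-NN votes unanimously; undersized k errors", {
  X <- matrix(rnorm(15 * 14), 15, 14)
  clf <- train_hb_classifier(classifier_spec("knn", knn_k = 11), X, rep(4L, 15))
  lik <- predict_likelihood(clf, rnorm(14))
  expect_equal(unname(lik[1, ]), c(0, 0, 0, 1, 0, 0))
  expect_error(train_hb_classifier(classifier_spec("knn", knn_k = 16), X,
                                   rep(4L, 15)), "exceeds")
  expect_error(train_hb_classifier(classifier_spec("svm"), X, rep(4L, 15)),
               "degenerate")
})

test_that("likelihoods are simplex-valid and grades argmax with low tie-break", {
  feats <- flux_features(rep(1:6, each = 6), noiseless_config())
  set.seed(33)
  Q <- matrix(runif(100 * 14, 1, 2), 100, 14)
  for (kind in c("knn", "svm", "nn")) {
    clf <- train_hb_classifier(classifier_spec(kind, epochs = 120), feats,
                               feats$hb_grade, seed = 2)
    lik <- predict_likelihood(clf, Q)
    expect_true(all(lik >= 0))
    expect_lt(max(abs(rowSums(lik) - 1)), 1e-9)
    expect_error(predict_likelihood(clf, rnorm(13)), "14")
  }
  # constructed exact tie resolves to the less severe grade
  clf <- train_hb_classifier(classifier_spec("knn", knn_k = 2),
                             rbind(rep(0, 14), rep(2, 14)), c(2L, 3L))
  expect_message(g <- predict_grade(clf, rep(1, 14)), "tie")
  expect_identical(g, 2L)
})

test_that("seeded network training is exactly reproducible", {
  feats <- flux_features(rep(1:6, each = 4), noiseless_config())
  sp <- classifier_spec("nn", epochs = 60)
  a <- train_hb_classifier(sp, feats, feats$hb_grade, seed = 9)
  b <- train_hb_classifier(sp, feats, feats$hb_grade, seed = 9)
  Q <- matrix(runif(10 * 14, 1, 2), 10, 14)
  expect_identical(predict_likelihood(a, Q), predict_likelihood(b, Q))
})

test_that("a well-separated severe case is graded VI", {
  feats <- flux_features(rep(1:6, each = 6), noiseless_config())
  probe <- as.numeric(feats[feats$hb_grade == 6, ][1, flowgrade:::feature_names()])
  for (kind in c("knn", "svm", "nn")) {
    clf <- train_hb_classifier(classifier_spec(kind), feats, feats$hb_grade,
                               seed = 3)
    expect_identical(predict_grade(clf, probe), 6L)
  }
})

test_that("patient-grouped folds partition the cohort without leakage", {
  feats <- flux_features(rep(1:6, each = 5), noiseless_config())
  for (seed in c(1, 7, 42)) {
    cv <- grouped_kfold_cv(classifier_spec("knn", knn_k = 3), feats, k = 5,
                           seed = seed)
    asg <- cv$assignment
    expect_setequal(asg$patient_id, feats$patient_id)
    expect_identical(anyDuplicated(asg$patient_id), 0L)
    expect_true(all(table(asg$fold) >= 1))
    expect_identical(sort(unique(asg$fold)), 1:5)
    expect_equal(sum(cv$confusion), nrow(feats))
  }
  expect_error(grouped_kfold_cv(classifier_spec("knn"), feats, k = 31), "31")
})

test_that("noise-free well-separated cohorts cross-validate perfectly", {
  # balanced cohort: every training fold then holds at least 11 identical
  # same-grade points, so the 11-neighbour vote is unanimous
  cfg <- noiseless_config(delta = 0.15)
  grades <- rep(1:6, each = 15)
  feats <- flux_features(grades, cfg)
  for (kind in c("knn", "svm", "nn")) {
    cv <- grouped_kfold_cv(classifier_spec(kind), feats, k = 5, seed = 1)
    expect_equal(cv$mean_accuracy, 1.0, info = kind)
  }
})

test_that("permuted labels score at chance level", {
  cfg <- noiseless_config()
  feats <- flux_features(rep(1:6, each = 5), cfg)
  accs <- vapply(1:8, function(s) {
    shuffled <- feats
    shuffled$hb_grade <- with_seed(s, sample(shuffled$hb_grade))
    grouped_kfold_cv(classifier_spec("nn", epochs = 150), shuffled, k = 5,
                     seed = s)$mean_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.05)
  expect_lte(mean(accs), 0.35)
})

test_that("1-NN memorises its own training points", {
  feats <- flux_features(rep(1:6, each = 4), noiseless_config())
  clf <- train_hb_classifier(classifier_spec("knn", knn_k = 1), feats,
                             feats$hb_grade)
  expect_equal(predict_grade(clf, feats), feats$hb_grade)
})
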