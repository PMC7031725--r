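#' House-Brackmann classifier specification
#'
#' The three classifier families used for HB grading. K-NN votes among
#' the k = 11 Euclidean nearest neighbours; the SVM uses a degree-2
#' polynomial kernel (one-vs-one pairwise machines; the six likelihoods
#' are the pairwise-vote fractions); the neural
#' network is a 14 - 32 - 16 - 6 multilayer perceptron (two hidden
#' layers, rectifier activations, softmax output) trained full-batch
#' with cross-entropy loss.
#'
#' @param kind `"knn"`, `"svm"` or `"nn"`.
#' @param knn_k neighbour count (default 11, odd).
#' @param svm_degree polynomial kernel degree (fixed default 2).
#' @param nn_hidden sizes of the two hidden layers.
#' @param epochs full-batch training epochs for the network.
#' @param learning_rate Adam step size for the network.
#' @param weight_decay L2 penalty on the network weights (not biases);
#'   with 80-patient training sets the network is heavily
#'   over-parameterised, and a small conventional decay keeps it on the
#'   affected/healthy contrast rather than memorising noise directions.
#' @param standardize fit per-feature zero-mean/unit-variance scaling on
#'   the training data; default on for svm/nn, off for knn.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "svm", "nn"), knn_k = 11L,
                            svm_degree = 2L, nn_hidden = c(32L, 16L),
                            epochs = 500L, learning_rate = 0.01,
                            weight_decay = 0.01, standardize = NULL) {
  kind <- match.arg(kind)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  if (length(nn_hidden) != 2L || any(nn_hidden < 1L))
    stop("the network must have exactly two hidden layers", call. = FALSE)
  if (is.null(standardize)) standardize <- kind != "knn"
  structure(list(kind = kind, knn_k = knn_k, svm_degree = as.integer(svm_degree),
                 nn_hidden = as.integer(nn_hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 standardize = standardize),
            class = "classifier_spec")
}

n_grades <- 6L

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features[feature_names()])
  features <- as.matrix(features)
  if (ncol(features) != 14L)
    stop(sprintf("features must have 14 columns, found %d", ncol(features)),
         call. = FALSE)
  storage.mode(features) <- "double"
  features
}

#' Train an HB-score classifier
#'
#' @param spec a [classifier_spec()].
#' @param features n x 14 matrix (or data frame with the feature columns)
#'   of relative regional perfusion vectors.
#' @param grades integer HB grades 1-6, one per row.
#' @param seed integer; training is deterministic given (spec, data, seed).
#' @return A `hb_classifier`.
#' @export
train_hb_classifier <- function(spec, features, grades, seed = 1L) {
  X <- as_feature_matrix(features)
  grades <- as.integer(grades)
  if (nrow(X) != length(grades))
    stop("feature and grade counts differ", call. = FALSE)
  if (any(grades < 1L | grades > n_grades))
    stop("grades must be in 1..6", call. = FALSE)
  classes <- sort(unique(grades))
  if (spec$kind != "knn" && length(classes) < 2L)
    stop("degenerate training set: fewer than 2 classes present",
         call. = FALSE)
  if (spec$kind == "knn" && spec$knn_k > nrow(X))
    stop(sprintf("knn_k = %d exceeds training size %d", spec$knn_k, nrow(X)),
         call. = FALSE)
  scaling <- NULL
  if (spec$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    scaling <- list(center = mu, scale = sdv)
    X <- scale(X, center = mu, scale = sdv)
  }
  fitted <- switch(spec$kind,
    knn = list(X = X, y = grades),
    svm = with_seed(seed, train_svm_multiclass(X, grades, spec)),
    nn  = train_mlp(X, grades, spec, seed))
  structure(list(spec = spec, fitted = fitted, classes = classes,
                 scaling = scaling, seed = as.integer(seed)),
            class = "hb_classifier")
}

train_svm_multiclass <- function(X, grades, spec) {
  e1071::svm(X, factor(grades, levels = sort(unique(grades))),
             type = "C-classification", kernel = "polynomial",
             degree = spec$svm_degree, gamma = 1 / ncol(X), coef0 = 1,
             cost = 1, scale = FALSE)
}

# pairwise one-vs-one vote fractions over the six grades
svm_vote_likelihood <- function(machine, X) {
  pr <- stats::predict(machine, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lik <- matrix(0, nrow(X), n_grades)
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- as.integer(pairs[[j]][1]); b <- as.integer(pairs[[j]][2])
    win <- ifelse(dv[, j] > 0, a, b)   # positive favours the first-named class
    lik[cbind(seq_len(nrow(X)), win)] <- lik[cbind(seq_len(nrow(X)), win)] + 1
  }
  lik / ncol(dv)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Predict the six-grade likelihood vector
#'
#' Returns, for each query, a nonnegative vector over the six HB grades
#' summing to 1: neighbour-vote fractions for K-NN, pairwise-vote
#' fractions for the SVM, and the network's softmax output.
#'
#' @param clf a trained `hb_classifier`.
#' @param features one feature vector (length 14) or an n x 14 matrix.
#' @return n x 6 matrix; column j is the likelihood of grade j.
#' @export
predict_likelihood <- function(clf, features) {
  if (is.null(dim(features)) && !is.data.frame(features)) {
    if (length(features) != 14L)
      stop(sprintf("expected a 14-element feature vector, found %d",
                   length(features)), call. = FALSE)
    features <- matrix(as.numeric(features), nrow = 1L)
  }
  X <- as_feature_matrix(features)
  if (!is.null(clf$scaling))
    X <- scale(X, center = clf$scaling$center, scale = clf$scaling$scale)
  lik <- switch(clf$spec$kind,
    knn = knn_likelihood(clf$fitted$X, clf$fitted$y, X, clf$spec$knn_k),
    svm = svm_vote_likelihood(clf$fitted, X),
    nn = mlp_forward(clf$fitted, X))
  colnames(lik) <- paste0("HB_", c("I", "II", "III", "IV", "V", "VI"))
  lik
}

knn_likelihood <- function(Xtrain, ytrain, Xquery, k) {
  d2 <- outer(rowSums(Xquery^2), rowSums(Xtrain^2), "+") -
    2 * Xquery %*% t(Xtrain)
  lik <- matrix(0, nrow(Xquery), n_grades)
  for (i in seq_len(nrow(Xquery))) {
    nb <- order(d2[i, ])[seq_len(k)]   # stable order breaks distance ties
    votes <- tabulate(ytrain[nb], nbins = n_grades)
    lik[i, ] <- votes / k
  }
  lik
}

#' Predict the HB grade
#'
#' The grade with maximal likelihood; exact ties break towards the lower
#' (less severe) grade and are reported via a message.
#'
#' @inheritParams predict_likelihood
#' @return Integer vector of grades in 1..6.
#' @export
predict_grade <- function(clf, features) {
  lik <- predict_likelihood(clf, features)
  apply(lik, 1L, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1L)
      message("likelihood tie between grades ",
              paste(top, collapse = ", "), "; returning the lowest")
    top[1]
  })
}

#' Patient-grouped k-fold cross-validation
#'
#' Patients are shuffled with the seed and partitioned into k folds at
#' the patient level, so no patient contributes to both training and
#' validation of the same fold. Each fold is held out once; accuracy is
#' the fraction of held-out patients whose predicted grade equals the
#' true grade, and the mean over folds is reported together with the
#' pooled 6 x 6 confusion matrix.
#'
#' @param spec a [classifier_spec()].
#' @param dataset data frame with columns `patient_id`, `hb_grade` and
#'   the 14 feature columns (one row per patient), e.g. from
#'   [extract_cohort_features()].
#' @param k number of folds (>= 2, at most the number of patients).
#' @param seed integer seed controlling the shuffle and fold-level
#'   training.
#' @return A `cv_report`: `k`, `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (6 x 6, rows = true), `assignment` (patient_id, fold,
#'   true and predicted grade).
#' @export
grouped_kfold_cv <- function(spec, dataset, k = 5L, seed = 1L) {
  k <- as.integer(k)
  n <- nrow(dataset)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d patients", k, n), call. = FALSE)
  if (anyDuplicated(dataset$patient_id))
    stop("dataset must have one row per patient", call. = FALSE)
  X <- as_feature_matrix(dataset)
  y <- as.integer(dataset$hb_grade)
  ord <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)  # patient-level partition
  pred <- integer(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold_of == f
    clf <- train_hb_classifier(spec, X[!hold, , drop = FALSE], y[!hold],
                               seed = seed * 100L + f)
    pred[hold] <- predict_grade(clf, X[hold, , drop = FALSE])
    fold_acc[f] <- mean(pred[hold] == y[hold])
  }
  confusion <- matrix(0L, n_grades, n_grades,
                      dimnames = list(true = 1:6, predicted = 1:6))
  for (i in seq_len(n)) confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  structure(list(k = k, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 confusion = confusion,
                 assignment = data.frame(patient_id = dataset$patient_id,
                                         fold = fold_of, true_grade = y,
                                         predicted_grade = pred,
                                         stringsAsFactors = FALSE)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold patient-grouped cross-validation\n", x$k))
  cat("  fold accuracies:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "),
      "\n")
  cat(sprintf("  mean accuracy: %.4f\n", x$mean_accuracy))
  invisible(x)
}

#' Serialise a cross-validation report
#'
#' @param report a `cv_report`.
#' @param path JSON path (the assignment table goes alongside as CSV when
#'   `csv` is given).
#' @param csv optional CSV path for the per-patient assignment.
#' @export
write_cv_report <- function(report, path, csv = NULL) {
  jsonlite::write_json(
    list(k = report$k, fold_accuracy = report$fold_accuracy,
         mean_accuracy = report$mean_accuracy,
         confusion = report$confusion),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (!is.null(csv))
    utils::write.csv(report$assignment, csv, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- two-hidden-layer perceptron (14 - h1 - h2 - 6), full-batch Adam ----

train_mlp <- function(X, grades, spec, seed) {
  h1 <- spec$nn_hidden[1]; h2 <- spec$nn_hidden[2]
  d <- ncol(X); n <- nrow(X)
  Y <- matrix(0, n, n_grades); Y[cbind(seq_len(n), grades)] <- 1
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * h1, sd = sqrt(2 / d)), d, h1), b1 = rep(0, h1),
    W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2), b2 = rep(0, h2),
    W3 = matrix(stats::rnorm(h2 * n_grades, sd = sqrt(2 / h2)), h2, n_grades),
    b3 = rep(0, n_grades)))
  m <- lapply(params, function(p) p * 0)
  v <- m
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; lr <- spec$learning_rate
  wd <- spec$weight_decay
  for (epoch in seq_len(spec$epochs)) {
    A1 <- sweep(X %*% params$W1, 2L, params$b1, "+"); Z1 <- pmax(A1, 0)
    A2 <- sweep(Z1 %*% params$W2, 2L, params$b2, "+"); Z2 <- pmax(A2, 0)
    A3 <- sweep(Z2 %*% params$W3, 2L, params$b3, "+")
    P <- softmax_rows(A3)
    G3 <- (P - Y) / n                       # d(cross-entropy)/d(logits)
    grads <- list(
      W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
      W3 = crossprod(Z2, G3), b3 = colSums(G3))
    G2 <- (G3 %*% t(params$W3)) * (A2 > 0)
    grads$W2 <- crossprod(Z1, G2); grads$b2 <- colSums(G2)
    G1 <- (G2 %*% t(params$W2)) * (A1 > 0)
    grads$W1 <- crossprod(X, G1); grads$b1 <- colSums(G1)
    for (nm in c("W1", "W2", "W3"))
      grads[[nm]] <- grads[[nm]] + 2 * wd * params[[nm]]
    for (nm in names(params)) {
      m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * grads[[nm]]
      v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1m^epoch)
      vhat <- v[[nm]] / (1 - b2m^epoch)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

mlp_forward <- function(params, X) {
  Z1 <- pmax(sweep(X %*% params$W1, 2L, params$b1, "+"), 0)
  Z2 <- pmax(sweep(Z1 %*% params$W2, 2L, params$b2, "+"), 0)
  softmax_rows(sweep(Z2 %*% params$W3, 2L, params$b3, "+"))
}
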