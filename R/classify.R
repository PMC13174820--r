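# Stratified cross-validated classification and DeLong AUC comparisons.

#' Mann-Whitney (midrank) AUC
#' @param scores numeric decision scores, higher = more positive.
#' @param labels 0/1 (or logical/two-level factor) class labels.
#' @return AUC in [0, 1].
#' @export
auc_midrank <- function(scores, labels) {
  y <- normalize_labels(labels)
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  as.integer(labels == u[2])
}

# DeLong structural components: V10 (per positive), V01 (per negative)
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  rall <- rank(c(pos, neg))
  rpos <- rank(pos); rneg <- rank(neg)
  auc <- (sum(rall[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  v10 <- (rall[seq_len(n1)] - rpos) / n0
  v01 <- 1 - (rall[n1 + seq_len(n0)] - rneg) / n1
  list(auc = auc, v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors for the same
#' subjects, using the structural-components estimate of the variance of
#' the AUC difference and a two-sided normal p-value.
#'
#' @param scores_a,scores_b paired decision scores (same subjects, same
#'   order).
#' @param labels binary class labels.
#' @return list of class \code{auc_comparison}: \code{auc_a}, \code{auc_b},
#'   \code{delta} (= auc_a - auc_b), \code{z}, \code{p},
#'   \code{degenerate}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must be paired (equal length)", call. = FALSE)
  y <- normalize_labels(labels)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n0
  delta <- ca$auc - cb$auc
  degenerate <- !is.finite(vd) || vd <= 0
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
                 p = p, var_delta = vd, degenerate = degenerate),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f (delta %.3f), z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

# seeded stratified fold assignment: within each class, shuffle and deal
# round-robin
stratified_folds <- function(y, n_splits, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    if (length(i) < n_splits)
      stop("each class needs at least n_splits members", call. = FALSE)
    folds[sample(i)] <- rep_len(seq_len(n_splits), length(i))
  }
  folds
}

#' Stratified cross-validated classification with pooled scoring
#'
#' Trains the requested classifier on each training split and concatenates
#' out-of-fold decision scores; one ROC/AUC is computed over the pooled
#' scores (as required for paired DeLong comparisons between models run on
#' the same folds). Deterministic given the seed.
#'
#' @param x numeric feature matrix (subjects x features).
#' @param labels binary labels.
#' @param model \code{"glm"} (logistic regression, default),
#'   \code{"svm_linear"}, \code{"svm_rbf"} (require e1071) or
#'   \code{"xgboost"}.
#' @param n_splits number of stratified folds (default 10).
#' @param seed RNG seed for the fold assignment (default 42).
#' @return list of class \code{cv_result}: \code{scores} (out-of-fold,
#'   subject order), \code{labels}, \code{folds}, \code{auc}, \code{model}.
#' @export
cv_classify <- function(x, labels, model = c("glm", "svm_linear", "svm_rbf",
                                             "xgboost"),
                        n_splits = 10L, seed = 42L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- normalize_labels(labels)
  folds <- stratified_folds(y, n_splits, seed)
  scores <- numeric(length(y))
  for (fd in seq_len(n_splits)) {
    tr <- folds != fd; te <- !tr
    scores[te] <- fit_score(x[tr, , drop = FALSE], y[tr],
                            x[te, , drop = FALSE], model)
  }
  structure(list(scores = scores, labels = y, folds = folds,
                 auc = auc_midrank(scores, y), model = model,
                 n_splits = n_splits, seed = seed),
            class = "cv_result")
}

fit_score <- function(xtr, ytr, xte, model) {
  dtr <- data.frame(.y = ytr, xtr)
  dte <- data.frame(xte)
  switch(model,
    glm = {
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dtr,
                                         family = stats::binomial()))
      suppressWarnings(stats::predict(fit, newdata = dte, type = "link"))
    },
    svm_linear = ,
    svm_rbf = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("e1071 is required for SVM models", call. = FALSE)
      fit <- e1071::svm(xtr, factor(ytr),
                        kernel = if (model == "svm_linear") "linear"
                                 else "radial",
                        probability = TRUE)
      pr <- attr(stats::predict(fit, xte, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    xgboost = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("xgboost is required for the xgboost model", call. = FALSE)
      fit <- xgboost::xgboost(data = xtr, label = ytr, nrounds = 50,
                              objective = "binary:logistic", verbose = 0,
                              nthread = 1)
      stats::predict(fit, xte)
    })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (%s, seed %d): pooled AUC = %.4f\n",
              x$n_splits, x$model, x$seed, x$auc))
  invisible(x)
}
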