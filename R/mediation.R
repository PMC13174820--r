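# Serial two-mediator mediation: X -> M1 -> M2 -> Y with covariates,
# nonparametric case-resampling bootstrap and bias-corrected CI.

med_coef <- function(Xd, y, col) {
  cf <- stats::lm.fit(Xd, y)$coefficients
  if (any(is.na(cf)))
    stop("collinear design in mediation fit", call. = FALSE)
  cf[col]
}

#' Serial two-mediator mediation with bootstrap CI
#'
#' Fits the three-path model with ordinary least squares:
#' \itemize{
#'   \item M1 ~ X + covariates (path a1)
#'   \item M2 ~ X + M1 + covariates (paths a3, a2)
#'   \item Y ~ X + M1 + M2 + covariates (paths c', d1, b)
#'   \item Y ~ X + covariates (total effect c)
#' }
#' The serial indirect effect is a1 * a2 * b. Its confidence interval comes
#' from a nonparametric case-resampling bootstrap with the bias-corrected
#' (BC) percentile method; the effect is flagged significant iff the CI
#' excludes zero. The OLS decomposition
#' c = c' + a1 * d1 + a3 * b + a1 * a2 * b holds exactly.
#'
#' @param x,m1,m2,y numeric vectors: exposure, first mediator, second
#'   mediator, outcome.
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param n_boot bootstrap draws (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @param standardize if TRUE, z-score x, m1, m2 and y before fitting (path
#'   coefficients then on standardized scales); default FALSE.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{serial_mediation} with paths \code{a1},
#'   \code{a2}, \code{a3}, \code{b}, \code{d1}, \code{c}, \code{c_prime},
#'   the \code{indirect} effect, \code{ci}, \code{boot} draws,
#'   \code{significant}, \code{n}, \code{n_boot}, \code{seed}.
#' @export
serial_mediation <- function(x, m1, m2, y, covariates = NULL,
                             n_boot = 5000L, seed = 1L,
                             standardize = FALSE, conf = 0.95) {
  d <- data.frame(x = x, m1 = m1, m2 = m2, y = y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    d <- cbind(d, covariates)
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- 4L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n < 10L * p)
    warning("fewer than 10 cases per parameter (n = ", n, "); estimates ",
            "may be unstable")
  if (n_boot < 100L) warning("n_boot < 100 gives unreliable intervals")
  if (standardize)
    for (v in c("x", "m1", "m2", "y")) d[[v]] <- as.numeric(scale(d[[v]]))
  cv <- if (is.null(covariates)) NULL else
    as.matrix(d[, -(1:4), drop = FALSE])
  if (abs(stats::cor(d$m1, d$m2)) > 1 - 1e-12)
    stop("collinear mediators", call. = FALSE)

  one <- rep(1, n)
  X1 <- cbind(`(Intercept)` = one, x = d$x, cv)
  X2 <- cbind(`(Intercept)` = one, x = d$x, m1 = d$m1, cv)
  X3 <- cbind(`(Intercept)` = one, x = d$x, m1 = d$m1, m2 = d$m2, cv)

  paths <- function(rows) {
    a1 <- med_coef(X1[rows, , drop = FALSE], d$m1[rows], "x")
    c2 <- stats::lm.fit(X2[rows, , drop = FALSE], d$m2[rows])$coefficients
    c3 <- stats::lm.fit(X3[rows, , drop = FALSE], d$y[rows])$coefficients
    c(a1 = unname(a1), a2 = unname(c2["m1"]), a3 = unname(c2["x"]),
      b = unname(c3["m2"]), d1 = unname(c3["m1"]), c_prime = unname(c3["x"]))
  }
  pt <- paths(seq_len(n))
  if (any(is.na(pt))) stop("collinear design in mediation fit", call. = FALSE)
  c_tot <- unname(med_coef(X1, d$y, "x"))
  indirect <- pt[["a1"]] * pt[["a2"]] * pt[["b"]]

  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    rows <- sample.int(n, n, replace = TRUE)
    pb <- tryCatch(paths(rows), error = function(e) rep(NA_real_, 6))
    pb[[1]] * pb[[2]] * pb[[4]]
  }, 0)
  boot <- boot[is.finite(boot)]

  # bias-corrected percentile interval
  z0 <- stats::qnorm(min(max(mean(boot < indirect), 1 / length(boot)),
                         1 - 1 / length(boot)))
  alpha <- (1 - conf) / 2
  lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  ci <- unname(stats::quantile(boot, c(lo_p, hi_p), type = 6))

  structure(list(a1 = pt[["a1"]], a2 = pt[["a2"]], a3 = pt[["a3"]],
                 b = pt[["b"]], d1 = pt[["d1"]],
                 c = c_tot, c_prime = pt[["c_prime"]],
                 indirect = indirect, ci = ci, conf = conf,
                 significant = ci[1] > 0 || ci[2] < 0,
                 boot = boot, n = n, n_boot = n_boot, seed = seed,
                 standardize = standardize),
            class = "serial_mediation")
}

#' @export
print.serial_mediation <- function(x, ...) {
  cat("Serial mediation X -> M1 -> M2 -> Y (n =", x$n, ")\n")
  cat(sprintf("  a1 = %.4g  a2 = %.4g  b = %.4g\n", x$a1, x$a2, x$b))
  cat(sprintf("  total c = %.4g  direct c' = %.4g\n", x$c, x$c_prime))
  cat(sprintf("  serial indirect a1*a2*b = %.4g, BC %g%% CI [%.4g, %.4g]%s\n",
              x$indirect, 100 * x$conf, x$ci[1], x$ci[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
summary.serial_mediation <- function(object, ...) {
  out <- data.frame(
    path = c("a1 (X->M1)", "a2 (M1->M2)", "a3 (X->M2)", "b (M2->Y)",
             "d1 (M1->Y)", "c (total)", "c' (direct)", "a1*a2*b (serial)"),
    estimate = c(object$a1, object$a2, object$a3, object$b, object$d1,
                 object$c, object$c_prime, object$indirect))
  attr(out, "ci") <- object$ci
  out
}
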