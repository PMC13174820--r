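# Covariate-adjusted association and group-difference tests used for
# cohort-level glymphatic analyses.

#' Covariate-adjusted standardized-beta regression
#'
#' Fits \code{scale(outcome) ~ scale(predictor) + covariates} by ordinary
#' least squares; outcome and predictor are z-scored (so the predictor's
#' coefficient is a standardized beta), covariates enter on their raw
#' scale. Two-sided p from the t distribution.
#'
#' @param outcome,predictor column names in \code{data}.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param data data frame; incomplete cases are dropped listwise.
#' @return list of class \code{std_beta}: \code{beta}, \code{t}, \code{p},
#'   \code{n}, \code{covariates}.
#' @export
standardized_beta <- function(outcome, predictor, covariates = character(),
                              data) {
  cols <- c(outcome, predictor, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(cols) + 2L)
    stop("too few complete cases for the requested model", call. = FALSE)
  if (stats::sd(d[[predictor]]) == 0)
    stop("constant predictor", call. = FALSE)
  d$.y <- as.numeric(scale(d[[outcome]]))
  d$.x <- as.numeric(scale(d[[predictor]]))
  fml <- stats::reformulate(c(".x", covariates), response = ".y")
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(beta = sm[".x", 1], t = sm[".x", 3], p = sm[".x", 4],
                 n = n, covariates = covariates),
            class = "std_beta")
}

#' @export
print.std_beta <- function(x, ...) {
  cat(sprintf("standardized beta = %.4f (t = %.3f, p = %.3g, n = %d)\n",
              x$beta, x$t, x$p, x$n))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1). Correction should be
#' applied within one family of comparisons at a time (e.g. within one
#' anatomical compartment).
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' ANCOVA across groups with covariate adjustment
#'
#' Tests the group factor after covariate adjustment by comparing the
#' nested models \code{outcome ~ covariates} and
#' \code{outcome ~ covariates + group} (type-"added-last" F test). With no
#' covariates this is one-way ANOVA. Adjusted group means are evaluated at
#' covariate means.
#'
#' @param outcome,group column names in \code{data}; \code{group} is
#'   coerced to a factor.
#' @param covariates character vector of covariate column names.
#' @param data data frame; incomplete cases dropped.
#' @return list of class \code{glymph_ancova}: \code{F}, \code{df},
#'   \code{p}, \code{adjusted_means}, \code{fit} (the full \code{lm}),
#'   \code{n}.
#' @export
ancova <- function(outcome, group, covariates = character(), data) {
  cols <- c(outcome, group, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  d[[group]] <- droplevels(as.factor(d[[group]]))
  if (nlevels(d[[group]]) < 2L)
    stop("ANCOVA needs at least two groups", call. = FALSE)
  full <- stats::lm(stats::reformulate(c(covariates, group),
                                       response = outcome), data = d)
  if (any(is.na(stats::coef(full))))
    stop("singular design", call. = FALSE)
  red <- stats::lm(stats::reformulate(if (length(covariates)) covariates
                                      else "1", response = outcome),
                   data = d)
  av <- stats::anova(red, full)
  # adjusted means: group predictions at covariate means
  nd <- data.frame(g = levels(d[[group]]))
  names(nd) <- group
  for (cv in covariates) nd[[cv]] <- mean(d[[cv]])
  adj <- stats::setNames(stats::predict(full, newdata = nd),
                         levels(d[[group]]))
  structure(list(F = av$F[2], df = c(av$Df[2], av$Res.Df[2]), p = av$`Pr(>F)`[2],
                 adjusted_means = adj, fit = full, n = nrow(d),
                 outcome = outcome, group = group, covariates = covariates,
                 data = d),
            class = "glymph_ancova")
}

#' @export
print.glymph_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA: F(%d, %d) = %.4f, p = %.4g (n = %d)\n",
              x$df[1], x$df[2], x$F, x$p, x$n))
  cat("adjusted means:\n")
  print(round(x$adjusted_means, 4))
  invisible(x)
}

#' Tukey HSD pairwise comparisons after ANCOVA
#'
#' Studentized-range adjusted p-values for all group pairs, using the
#' covariate-adjusted means and the residual variance of the ANCOVA fit.
#'
#' @param fit a \code{\link{ancova}} result.
#' @return data frame with columns \code{pair}, \code{diff} (adjusted mean
#'   difference), \code{p_adj}.
#' @export
tukey_hsd <- function(fit) {
  stopifnot(inherits(fit, "glymph_ancova"))
  d <- fit$data
  g <- droplevels(as.factor(d[[fit$group]]))
  lev <- levels(g)
  k <- length(lev)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  mse <- sum(stats::residuals(fit$fit)^2) / fit$fit$df.residual
  nn <- table(g)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- fit$adjusted_means[lev[j]] - fit$adjusted_means[lev[i]]
    se <- sqrt(mse / 2 * (1 / nn[lev[i]] + 1 / nn[lev[j]]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, k, fit$fit$df.residual, lower.tail = FALSE)
    out <- rbind(out, data.frame(pair = paste(lev[j], "-", lev[i]),
                                 diff = unname(diff), p_adj = unname(p)))
  }
  out
}

#' Rank-based ANCOVA with pairwise Wilcoxon tests
#'
#' Nonparametric fallback for non-normal outcomes: the outcome is replaced
#' by mid-ranks and the \code{\link{ancova}} F test applied to the ranks;
#' post hoc pairwise Wilcoxon rank-sum tests (exact where feasible, normal
#' approximation with tie correction otherwise).
#'
#' @inheritParams ancova
#' @return list: \code{F}, \code{p} (rank-ANCOVA), \code{pairwise} (data
#'   frame of group pair and Wilcoxon p).
#' @export
rank_ancova_wilcoxon <- function(outcome, group, covariates = character(),
                                 data) {
  cols <- c(outcome, group, covariates)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  d$.r <- rank(d[[outcome]])
  ra <- ancova(".r", group, covariates, d)
  g <- droplevels(as.factor(d[[group]]))
  lev <- levels(g)
  pw <- NULL
  for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
    w <- stats::wilcox.test(d[[outcome]][g == lev[i]],
                            d[[outcome]][g == lev[j]])
    pw <- rbind(pw, data.frame(pair = paste(lev[j], "-", lev[i]),
                               p = w$p.value))
  }
  list(F = ra$F, p = ra$p, pairwise = pw)
}

#' Mean arterial pressure
#'
#' MAP = (2 * diastolic + systolic) / 3, in the units of the inputs (mmHg).
#'
#' @param systolic,diastolic positive blood pressures (mmHg); vectorized.
#' @return numeric MAP.
#' @export
derive_map <- function(systolic, diastolic) {
  if (any(!is.na(systolic) & systolic <= 0) ||
      any(!is.na(diastolic) & diastolic <= 0))
    stop("blood pressures must be positive", call. = FALSE)
  (2 * diastolic + systolic) / 3
}

#' Amyloid-PET positivity call from composite SUVR
#'
#' Strict-greater-than thresholding with tracer-specific cutoffs:
#' florbetapir (AV45) composite SUVR > 1.11, florbetaben (FBB) SUVR >
#' 1.478.
#'
#' @param suvr numeric composite SUVR (vectorized).
#' @param tracer \code{"AV45"} or \code{"FBB"} (scalar or per-element).
#' @return logical positivity.
#' @export
amyloid_positivity <- function(suvr, tracer) {
  thr <- c(AV45 = 1.11, FBB = 1.478)
  tracer <- rep_len(as.character(tracer), length(suvr))
  if (!all(tracer %in% names(thr)))
    stop("unknown tracer; use AV45 or FBB", call. = FALSE)
  suvr > unname(thr[tracer])
}
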