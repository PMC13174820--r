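# Choice of how many largest pAs components per ROI to analyze: sensitivity
# (summed |t| of clinical associations) against subject inclusion.

#' Optimize the number of largest pAs components per ROI
#'
#' For each candidate n, computes covariate-adjusted standardized-beta
#' regressions of the subject-level FWAD and FWVF metrics (obtained with
#' the n largest components) on each clinical variable, sums the absolute t
#' statistics across variables and metrics, and reports the n maximizing
#' that sum together with the fraction of subjects retained. When the
#' predictor is itself one of the covariates (e.g. age) it is dropped from
#' the covariate list for that regression. Exact ties break toward smaller
#' n (greater subject inclusion).
#'
#' @param metrics long data frame with columns \code{subject}, \code{n},
#'   \code{FWAD}, \code{FWVF}: the subject-level pAs metrics computed with
#'   each candidate number of components (NA when the subject lacks that
#'   many components).
#' @param pheno data frame with \code{subject}, the clinical variables and
#'   the covariates.
#' @param clinical_vars character vector of clinical variable names.
#' @param covariates adjustment covariates (default age, sex, education).
#' @param ns candidate values of n (default: those present in
#'   \code{metrics}).
#' @return list of class \code{n_selection}: \code{best_n}, \code{curve}
#'   (data frame n, sum_abs_t, inclusion).
#' @export
optimize_n <- function(metrics, pheno, clinical_vars,
                       covariates = c("age", "sex", "education"),
                       ns = sort(unique(metrics$n))) {
  if (!length(ns)) stop("empty candidate list for n", call. = FALSE)
  stopifnot(all(c("subject", "n", "FWAD", "FWVF") %in% names(metrics)))
  curve <- data.frame(n = ns, sum_abs_t = NA_real_, inclusion = NA_real_)
  n_subj <- length(unique(metrics$subject))
  for (i in seq_along(ns)) {
    mi <- metrics[metrics$n == ns[i], , drop = FALSE]
    mi <- mi[stats::complete.cases(mi[, c("FWAD", "FWVF")]), , drop = FALSE]
    d <- merge(mi, pheno, by = "subject")
    curve$inclusion[i] <- nrow(mi) / n_subj
    tot <- 0
    for (metric in c("FWAD", "FWVF"))
      for (v in clinical_vars) {
        covs <- setdiff(covariates, v)
        sb <- tryCatch(standardized_beta(metric, v, covs, d),
                       error = function(e) NULL)
        if (!is.null(sb)) tot <- tot + abs(sb$t)
      }
    curve$sum_abs_t[i] <- tot
  }
  ord <- order(-curve$sum_abs_t, curve$n)
  structure(list(best_n = curve$n[ord[1]], curve = curve),
            class = "n_selection")
}

#' @export
print.n_selection <- function(x, ...) {
  cat("n-largest selection: best n =", x$best_n, "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}
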