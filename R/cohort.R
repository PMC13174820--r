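# Synthetic cohorts: phenotype tables with realistic cardiometabolic
# marginals, subject-level glymphatic features with planted standardized
# associations, and a planted serial-mediation chain.

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Cohort specification
#'
#' Defaults emulate a cognitively normal aging cohort: marginal means/SDs
#' for the cardiometabolic variables follow published summary statistics
#' for such samples (age 58.6 (14.1), BMI 27.1 (4.8), SBP 129 (16),
#' DBP 79 (10), HDL 60 (16), HbA1c 5.4 (0.5), triglycerides 108 (68),
#' glucose 102 (18), PSQI 4.7 (2.7), MoCA 26.4 (2.6)). Planted effects are
#' standardized slopes linking CMS variables to the pAs metrics; the
#' serial-mediation chain X (diastolic BP) -> M1 (precuneus pAs-FWAD) ->
#' M2 (precuneus amyloid SUVR) -> Y (MoCA) is generated on standardized
#' scales with the stated path truths and then mapped affinely onto
#' field-plausible units (affine maps leave standardized path coefficients
#' unchanged).
#'
#' @param n number of subjects.
#' @param fwad_effects named standardized slopes of CMS variables on
#'   whole-brain pAs-FWAD.
#' @param fwvf_effects named standardized slopes on pAs-FWVF.
#' @param med_paths named vector with elements a1, a2, b, c_prime: the
#'   serial-mediation path truths (standardized).
#' @param med_noise_sd residual SD of each mediation equation
#'   (standardized scale).
#' @param noise_sd residual SD of the feature equations (standardized).
#' @param group_props proportions of CN/MCI/AD diagnoses (sum to 1).
#' @param fwvf_group_offset FWVF offset (in SD) added per diagnostic stage
#'   beyond CN.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n = 546L,
                        fwad_effects = c(bmi = -0.36, diastolic = -0.17,
                                         hdl = 0.17),
                        fwvf_effects = c(age = 0.48, bmi = 0.19,
                                         triglycerides = 0.17,
                                         hdl = -0.15),
                        med_paths = c(a1 = 0.5, a2 = 0.5, b = 0.5,
                                      c_prime = 0),
                        med_noise_sd = 0.5,
                        noise_sd = 0.8,
                        group_props = c(CN = 0.55, MCI = 0.39, AD = 0.06),
                        fwvf_group_offset = 0.5) {
  if (abs(sum(group_props) - 1) > 1e-8)
    stop("group proportions must sum to 1", call. = FALSE)
  if (noise_sd <= 0 || med_noise_sd <= 0)
    stop("noise SDs must be positive", call. = FALSE)
  structure(list(n = as.integer(n), fwad_effects = fwad_effects,
                 fwvf_effects = fwvf_effects, med_paths = med_paths,
                 med_noise_sd = med_noise_sd, noise_sd = noise_sd,
                 group_props = group_props,
                 fwvf_group_offset = fwvf_group_offset),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a phenotype table from the specification's marginals, builds
#' subject-level glymphatic features as linear functions of the z-scored
#' planted predictors plus Gaussian noise, generates the serial-mediation
#' chain, and returns the ground truth alongside.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed.
#' @return list: \code{pheno} (phenotype data frame), \code{features}
#'   (subject-level feature data frame including the columns used by
#'   \code{\link{build_feature_sets}}), \code{truth} (planted effects and
#'   paths).
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$n
  pheno <- data.frame(
    subject = sprintf("S%04d", seq_len(n)),
    age = rtrunc_norm(n, 58.6, 14.1, 36, 100),
    sex = stats::rbinom(n, 1, 0.57),             # 1 = female
    education = round(rtrunc_norm(n, 16.7, 2.3, 8, 22)),
    bmi = rtrunc_norm(n, 27.1, 4.8, 16, 50),
    systolic = rtrunc_norm(n, 129.1, 16.4, 90, 200),
    diastolic = rtrunc_norm(n, 79.3, 10.5, 50, 120),
    hdl = rtrunc_norm(n, 60.1, 16.5, 20, 130),
    hba1c = rtrunc_norm(n, 5.36, 0.53, 4, 9),
    total_cholesterol = rtrunc_norm(n, 198.7, 36.4, 100, 350),
    triglycerides = rtrunc_norm(n, 108.4, 68.3, 30, 500),
    glucose = rtrunc_norm(n, 101.9, 17.9, 60, 250),
    psqi = round(rtrunc_norm(n, 4.68, 2.69, 0, 21)),
    apoe4 = stats::rbinom(n, 1, 0.3)
  )
  pheno$map <- derive_map(pheno$systolic, pheno$diastolic)
  dx <- sample(factor(rep(names(spec$group_props),
                          round(spec$group_props * n))[seq_len(n)],
                      levels = names(spec$group_props)))
  pheno$diagnosis <- dx

  z <- function(v) as.numeric(scale(v))
  zp <- list(age = z(pheno$age), bmi = z(pheno$bmi),
             diastolic = z(pheno$diastolic), systolic = z(pheno$systolic),
             hdl = z(pheno$hdl), hba1c = z(pheno$hba1c),
             triglycerides = z(pheno$triglycerides),
             glucose = z(pheno$glucose), psqi = z(pheno$psqi))
  planted <- function(effects) {
    s <- rep(0, n)
    for (v in names(effects)) s <- s + effects[[v]] * zp[[v]]
    s + stats::rnorm(n, 0, spec$noise_sd)
  }

  # standardized latent features
  fwad_z <- planted(spec$fwad_effects)
  fwvf_z <- planted(spec$fwvf_effects) +
    spec$fwvf_group_offset * (as.integer(dx) - 1L)
  alps_z <- -0.37 * zp$age + stats::rnorm(n, 0, spec$noise_sd)

  # serial-mediation chain on standardized scales
  p <- spec$med_paths
  xz <- zp$diastolic
  m1 <- p[["a1"]] * xz + stats::rnorm(n, 0, spec$med_noise_sd)
  m2 <- p[["a2"]] * m1 + stats::rnorm(n, 0, spec$med_noise_sd)
  yv <- p[["b"]] * m2 + p[["c_prime"]] * xz +
    stats::rnorm(n, 0, spec$med_noise_sd)

  to_scale <- function(zv, mean, sd) mean + sd * zv
  features <- data.frame(
    subject = pheno$subject,
    pas_FWAD_precuneus = to_scale(m1, 3.4e-3, 2.0e-4),
    pas_FWAD_adsig = to_scale(fwad_z, 3.4e-3, 2.0e-4),
    pas_FWAD_wholebrain = to_scale(fwad_z, 3.4e-3, 2.0e-4),
    pas_FWVF_precuneus = pmin(pmax(to_scale(fwvf_z, 0.55, 0.08), 0), 1),
    pas_FWVF_adsig = pmin(pmax(to_scale(fwvf_z, 0.55, 0.08), 0), 1),
    pas_FWVF_wholebrain = pmin(pmax(to_scale(fwvf_z, 0.55, 0.08), 0), 1),
    wm_FWVF_precuneus = pmin(pmax(to_scale(fwvf_z, 0.18, 0.04), 0), 1),
    wm_FWVF_adsig = pmin(pmax(to_scale(fwvf_z, 0.18, 0.04), 0), 1),
    wm_FWVF_wholebrain = pmin(pmax(to_scale(fwvf_z, 0.18, 0.04), 0), 1),
    alps = to_scale(alps_z, 1.45, 0.15),
    abeta_suvr_precuneus = to_scale(m2, 1.29, 0.32),
    abeta_suvr_adsig = to_scale(m2, 1.16, 0.27),
    abeta_suvr_wholebrain = to_scale(m2, 1.20, 0.27),
    tau_suvr_precuneus = to_scale(0.5 * m2 + 0.5 * stats::rnorm(n),
                                  1.19, 0.23),
    tau_suvr_adsig = to_scale(0.5 * m2 + 0.5 * stats::rnorm(n), 1.32, 0.32),
    tau_suvr_wholebrain = to_scale(0.5 * m2 + 0.5 * stats::rnorm(n),
                                   1.19, 0.23)
  )
  pheno$moca <- round(pmin(pmax(to_scale(yv, 26.4, 2.55), 0), 30), 1)
  pheno$mmse <- round(pmin(pmax(to_scale(yv, 27.9, 2.68), 0), 30))
  pheno$abeta_suvr <- features$abeta_suvr_wholebrain
  pheno$amyloid_positive <- amyloid_positivity(pheno$abeta_suvr, "FBB")

  list(pheno = pheno, features = features,
       truth = list(fwad_effects = spec$fwad_effects,
                    fwvf_effects = spec$fwvf_effects,
                    med_paths = spec$med_paths,
                    med_chain = list(x = "diastolic (z)",
                                     m1 = "pas_FWAD_precuneus",
                                     m2 = "abeta_suvr_precuneus",
                                     y = "moca"),
                    fwvf_group_offset = spec$fwvf_group_offset,
                    seed = seed))
}

#' Synthetic per-component cohort for the n-largest selection procedure
#'
#' Each subject carries a variable number of pAs components. Only the four
#' largest share the subject-level latent signal (which is linearly linked
#' to the clinical variable); smaller components are pure noise, so
#' including them dilutes the clinical association while requiring more
#' components excludes subjects. Produces the long metrics-by-n table
#' consumed by \code{\link{optimize_n}}.
#'
#' @param n_subjects cohort size.
#' @param slope standardized slope linking the clinical variable to the
#'   subject-level latent signal.
#' @param comp_noise SD of the per-component measurement noise around the
#'   latent signal; large relative to the signal, so pooling all four
#'   signal-bearing components is materially better than using fewer.
#' @param n_signal number of (largest) components carrying signal.
#' @param max_components largest possible component count per subject.
#' @param comp_probs probabilities of a subject carrying
#'   \code{(n_signal - 1):max_components} components; the default keeps
#'   inclusion high (~95 percent) at \code{n_signal} and lets it fall for
#'   larger counts, the trade-off the selection procedure navigates.
#' @param seed integer seed.
#' @return list: \code{metrics} (subject, n, FWAD, FWVF), \code{pheno}
#'   (subject, clinical variable \code{bmi}, covariates age/sex/education).
#' @export
make_component_cohort <- function(n_subjects = 300L, slope = 0.6,
                                  comp_noise = 2, n_signal = 4L,
                                  max_components = 8L,
                                  comp_probs = c(0.02, 0.18, 0.2, 0.2,
                                                 0.2, 0.2),
                                  seed = 1L) {
  set.seed(seed)
  pheno <- data.frame(
    subject = sprintf("S%04d", seq_len(n_subjects)),
    age = rtrunc_norm(n_subjects, 58.6, 14.1, 36, 100),
    sex = stats::rbinom(n_subjects, 1, 0.57),
    education = round(rtrunc_norm(n_subjects, 16.7, 2.3, 8, 22)),
    bmi = rtrunc_norm(n_subjects, 27.1, 4.8, 16, 50)
  )
  u <- slope * as.numeric(scale(pheno$bmi)) +
    sqrt(1 - slope^2) * stats::rnorm(n_subjects)
  counts <- (n_signal - 1L):max_components
  stopifnot(length(comp_probs) == length(counts))
  n_comp <- sample(counts, n_subjects, replace = TRUE, prob = comp_probs)
  rows <- NULL
  for (i in seq_len(n_subjects)) {
    vals_ad <- c(u[i] + stats::rnorm(min(n_comp[i], n_signal), 0,
                                     comp_noise),
                 stats::rnorm(max(n_comp[i] - n_signal, 0), 0, comp_noise))
    vals_vf <- c(u[i] + stats::rnorm(min(n_comp[i], n_signal), 0,
                                     comp_noise),
                 stats::rnorm(max(n_comp[i] - n_signal, 0), 0, comp_noise))
    for (nn in 1:max_components) {
      rows <- rbind(rows, data.frame(
        subject = pheno$subject[i], n = nn,
        FWAD = if (n_comp[i] >= nn) mean(vals_ad[seq_len(nn)]) else NA,
        FWVF = if (n_comp[i] >= nn) mean(vals_vf[seq_len(nn)]) else NA))
    }
  }
  list(metrics = rows, pheno = pheno)
}
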