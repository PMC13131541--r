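#' Build the standard covariate design for cohort regressions
#'
#' Assembles the regression covariates used throughout the analysis: group
#' (reference = controls), age, sex, education, BMI, the two
#' levodopa-exposure indicators, four comorbidity flags, and log-transformed
#' post-mortem interval and storage duration (logs capture exponential
#' time-related decay).
#'
#' @param subjects subject table (post-imputation).
#' @param processed optional `processed_matrix` providing DOPA z-values for
#'   exposure indicators; if NULL and the table carries `levodopa_exposed`,
#'   that flag is routed into the indicators instead.
#' @param control_group reference group label.
#' @param merge_groups optional named list recoding groups, e.g.
#'   `list("Dementia" = c("AD-D", "PD-D"))` to test merged contrasts.
#' @return data.frame ready for [hetlm()], with attribute `group_levels`.
#' @export
build_design <- function(subjects, processed = NULL,
                         control_group = "HC-CN", merge_groups = NULL) {
  d <- data.frame(
    group = subjects$group,
    age = subjects$age,
    sex = as.integer(subjects$sex == "F"),
    education = subjects$education,
    bmi = subjects$bmi,
    hyperlipidemia = subjects$hyperlipidemia,
    diabetes = subjects$diabetes,
    renal_insufficiency = subjects$renal_insufficiency,
    hypothyroidism = subjects$hypothyroidism,
    log_pmi = log(subjects$pmi_hours),
    log_storage = log(subjects$storage_years),
    stringsAsFactors = FALSE
  )
  if (!is.null(processed) && "DOPA" %in% colnames(processed$z)) {
    di <- derive_dopa_indicators(processed$z[subjects$subject_id, "DOPA"],
                                 subjects$group,
                                 control_group = control_group)
  } else if ("levodopa_exposed" %in% names(subjects)) {
    di <- data.frame(
      dopa_pdd = as.integer(subjects$levodopa_exposed == 1L &
                              subjects$group == "PD-D"),
      dopa_pdnd = as.integer(subjects$levodopa_exposed == 1L &
                               subjects$group %in% c("PD-MCI", "PD-CN")))
  } else {
    di <- data.frame(dopa_pdd = 0L, dopa_pdnd = 0L)
  }
  d <- cbind(d, di)
  if (!is.null(merge_groups)) {
    for (new in names(merge_groups))
      d$group[d$group %in% merge_groups[[new]]] <- new
  }
  d$group <- stats::relevel(factor(d$group), ref = control_group)
  attr(d, "group_levels") <- levels(d$group)
  d
}

# Drop covariates that are constant in the fitted subset (e.g. a comorbidity
# absent from a small cohort) so the design stays full rank.
active_covariates <- function(design, covariates) {
  keep <- vapply(covariates, function(v)
    length(unique(design[[v]][!is.na(design[[v]])])) > 1, logical(1))
  covariates[keep]
}

default_covariates <- c("age", "sex", "education", "bmi",
                        "dopa_pdd", "dopa_pdnd",
                        "hyperlipidemia", "diabetes", "renal_insufficiency",
                        "hypothyroidism", "log_pmi", "log_storage")

#' Differential metabolite analysis across subject groups
#'
#' One group-heteroscedastic regression per metabolite: metabolite z-values
#' as the response, subject-group indicators (against the control reference)
#' plus the standard covariates as regressors, residual variance free per
#' group. Group-term p-values are Benjamini-Hochberg adjusted across
#' metabolites within each group contrast (one FDR family per contrast
#' column). Merged-group contrasts (e.g. all demented subjects together) are
#' requested through `merge_groups`.
#'
#' @param processed `processed_matrix` from [preprocess_assay()].
#' @param subjects subject table.
#' @param covariates covariate column names present in the design.
#' @param merge_groups see [build_design()].
#' @param control_group reference group.
#' @param exclude metabolites to skip in addition to LOD-excluded ones
#'   (DOPA, the exposure marker, is skipped by default).
#' @return data.frame: response, term, beta, se, p, fdr.
#' @export
run_differential <- function(processed, subjects,
                             covariates = default_covariates,
                             merge_groups = NULL,
                             control_group = "HC-CN",
                             exclude = "DOPA") {
  design <- build_design(subjects, processed, control_group, merge_groups)
  covariates <- active_covariates(design, covariates)
  mets <- setdiff(colnames(processed$z), c(processed$excluded, exclude))
  rows <- list()
  for (m in mets) {
    d <- cbind(design, .y = processed$z[subjects$subject_id, m])
    fml <- stats::reformulate(c("group", covariates), response = ".y")
    fit <- hetlm(fml, d, variance_group = "group")
    gterms <- grep("^group", names(coef(fit)), value = TRUE)
    rows[[m]] <- data.frame(
      response = m,
      term = sub("^group", "", gterms),
      beta = unname(coef(fit)[gterms]),
      se = unname(fit$se[gterms]),
      p = unname(fit$pvals[gterms]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (tm in unique(out$term)) {
    sel <- out$term == tm
    out$fdr[sel] <- bh_adjust(out$p[sel])
  }
  out
}

#' Association of a response with features added one at a time
#'
#' Runs the standard adjusted regression once per feature, with the feature
#' as an additional regressor (e.g. progression score on each B vitamin, or
#' homocysteine/betaine on each vitamin), and reports the feature term with
#' FDR across features. Optionally restricted to a subject subset.
#'
#' @param y numeric response vector aligned with `subjects`.
#' @param features numeric matrix subjects x features (added one at a time).
#' @param subjects subject table.
#' @param processed optional `processed_matrix` for DOPA indicators.
#' @param covariates covariate names; group indicators are always kept.
#' @param subset optional logical vector restricting the analysis.
#' @param control_group reference group.
#' @return data.frame: response, term (feature), beta, se, p, fdr.
#' @export
run_covariate_assoc <- function(y, features, subjects, processed = NULL,
                                covariates = default_covariates,
                                subset = NULL, control_group = "HC-CN") {
  design <- build_design(subjects, processed, control_group)
  if (!is.null(subset)) {
    design <- design[subset, , drop = FALSE]
    y <- y[subset]
    features <- features[subset, , drop = FALSE]
  }
  covariates <- active_covariates(design, covariates)
  rows <- list()
  for (f in colnames(features)) {
    d <- cbind(design, .y = y, .x = features[, f])
    n_ok <- sum(stats::complete.cases(d))
    p_needed <- length(covariates) + length(unique(design$group)) + 2
    if (n_ok <= p_needed + length(unique(design$group))) {
      warning("subset too small for feature ", f, "; skipped", call. = FALSE)
      next
    }
    fml <- stats::reformulate(c("group", covariates, ".x"), response = ".y")
    fit <- hetlm(fml, d, variance_group = "group")
    rows[[f]] <- data.frame(
      response = "y", term = f,
      beta = unname(coef(fit)[".x"]), se = unname(fit$se[".x"]),
      p = unname(fit$pvals[".x"]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(response = character(0),
                                      term = character(0), beta = numeric(0),
                                      se = numeric(0), p = numeric(0),
                                      fdr = numeric(0)))
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out
}
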