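#' Fit a quadratic calibration curve
#'
#' Least-squares fit of signal = a + b*conc + c*conc^2 to calibrator wells.
#' With fewer than 3 distinct concentrations the quadratic is not
#' identifiable and the curve falls back to the identity (uncalibrated
#' relative mode), as used for compounds lacking external standards.
#'
#' @param concentration,signal numeric vectors of calibrator points.
#' @return object of class `calibration_curve` with coefficients, the valid
#'   concentration range and residual summary. Identity fallback has
#'   `type = "identity"`.
#' @export
fit_calibration <- function(concentration, signal) {
  ok <- is.finite(concentration) & is.finite(signal)
  concentration <- concentration[ok]; signal <- signal[ok]
  if (length(unique(concentration)) < 3) {
    warning("fewer than 3 distinct calibrator concentrations; identity fallback",
            call. = FALSE)
    return(structure(list(type = "identity", coefficients = c(a = 0, b = 1, c = 0),
                          range = c(-Inf, Inf), rss = NA_real_),
                     class = "calibration_curve"))
  }
  fit <- stats::lm(signal ~ concentration + I(concentration^2))
  cf <- stats::setNames(stats::coef(fit), c("a", "b", "c"))
  structure(list(type = "quadratic", coefficients = cf,
                 range = range(concentration),
                 rss = sum(stats::resid(fit)^2)),
            class = "calibration_curve")
}

#' Invert a calibration curve: signal to concentration
#'
#' Solves the quadratic response for concentration, taking the root on the
#' monotone branch covering the calibrated range. Identity curves return the
#' signal unchanged.
#'
#' @param curve a [fit_calibration()] result.
#' @param signal numeric vector of signals.
#' @return numeric concentrations.
#' @export
apply_calibration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$type == "identity") return(signal)
  a <- curve$coefficients[["a"]]; b <- curve$coefficients[["b"]]
  cc <- curve$coefficients[["c"]]
  if (abs(cc) < 1e-12 * max(1, abs(b))) return((signal - a) / b)
  disc <- pmax(b^2 - 4 * cc * (a - signal), 0)
  r1 <- (-b + sqrt(disc)) / (2 * cc)
  r2 <- (-b - sqrt(disc)) / (2 * cc)
  mid <- mean(curve$range)
  ifelse(abs(r1 - mid) <= abs(r2 - mid), r1, r2)
}

#' Limit of detection from blank wells
#'
#' LOD = blank mean + 3.09 x blank SD (sample SD), the estimated 99.9th
#' percentile of the blank signal distribution under normality.
#'
#' @param blank_signals numeric vector, length >= 2.
#' @return scalar LOD.
#' @export
compute_lod <- function(blank_signals) {
  blank_signals <- blank_signals[is.finite(blank_signals)]
  if (length(blank_signals) < 2) stop("need >= 2 blanks", call. = FALSE)
  mean(blank_signals) + 3.09 * stats::sd(blank_signals)
}

#' Flag metabolites consistently below the limit of detection
#'
#' A metabolite is excluded when strictly more than half of its sample wells
#' fall below their plate-specific LOD.
#'
#' @param signals numeric matrix subjects x metabolites of raw signals.
#' @param lods matrix plates x metabolites of LOD values.
#' @param plate integer plate assignment per subject (row of `signals`).
#' @return named logical vector: TRUE = excluded.
#' @export
flag_below_lod <- function(signals, lods, plate) {
  stopifnot(nrow(signals) == length(plate))
  vapply(colnames(signals), function(m) {
    below <- signals[, m] < lods[plate, m]
    mean(below, na.rm = TRUE) > 0.5
  }, logical(1))
}

#' Group-respecting plate normalization
#'
#' Removes plate-level location/scale differences while preserving group mean
#' differences: (1) per-group means are estimated on pooled data and
#' subtracted; (2) within each plate the residuals are centred on their mean
#' and rescaled by the ratio of the pooled residual SD to the plate residual
#' SD, so a pure plate offset is removed exactly; (3) group means are added
#' back. Remote outliers are handled downstream by Tukey fencing, so the
#' moment-based alignment is not distorted in the processed output. Plates
#' with fewer than 3 samples are left unadjusted with a warning.
#'
#' @param x numeric vector (one metabolite) or matrix (subjects x
#'   metabolites).
#' @param plate plate assignment per subject.
#' @param group group label per subject.
#' @return object of the same shape as `x`.
#' @export
normalize_across_plates <- function(x, plate, group) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x)))
      out[, j] <- normalize_across_plates(x[, j], plate, group)
    return(out)
  }
  stopifnot(length(x) == length(plate), length(x) == length(group))
  plates <- unique(plate)
  if (length(plates) < 2) return(x)
  gm <- tapply(x, group, mean, na.rm = TRUE)
  r <- x - gm[group]
  pooled_sd <- stats::sd(r, na.rm = TRUE)
  for (pl in plates) {
    sel <- plate == pl
    if (sum(sel) < 3) {
      warning("plate ", pl, " has fewer than 3 samples; left unadjusted",
              call. = FALSE)
      next
    }
    mu <- mean(r[sel], na.rm = TRUE)
    psd <- stats::sd(r[sel], na.rm = TRUE)
    sc <- if (psd > 0 && pooled_sd > 0) pooled_sd / psd else 1
    r[sel] <- (r[sel] - mu) * sc
  }
  as.vector(gm[group] + r)
}

#' Box-Cox transformation: profile-likelihood lambda and transform
#'
#' `estimate_boxcox_lambda()` maximizes the profile Gaussian log-likelihood
#' of the Box-Cox family over lambda in `[-3, 3]`;
#' `apply_boxcox()` computes (x^lambda - 1)/lambda, log(x) at lambda = 0.
#'
#' When `groups` is supplied the likelihood is profiled with group-specific
#' means (Box-Cox regression on the group factor), so genuine group location
#' shifts do not masquerade as skewness and bias the lambda estimate.
#'
#' @param x strictly positive numeric vector.
#' @param groups optional group labels; lambda is then estimated from the
#'   within-group variation.
#' @param lower,upper search bounds for lambda.
#' @return `estimate_boxcox_lambda`: scalar lambda; `apply_boxcox`:
#'   transformed vector.
#' @export
estimate_boxcox_lambda <- function(x, groups = NULL, lower = -3, upper = 3) {
  ok <- is.finite(x)
  x <- x[ok]
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values", call. = FALSE)
  g <- if (is.null(groups)) rep(1L, length(x)) else as.integer(factor(groups[ok]))
  n <- length(x)
  slog <- sum(log(x))
  ll <- function(lam) {
    z <- apply_boxcox(x, lam)
    r <- z - stats::ave(z, g)
    -n / 2 * log(mean(r^2)) + (lam - 1) * slog
  }
  stats::optimize(ll, c(lower, upper), maximum = TRUE, tol = 1e-6)$maximum
}

#' @rdname estimate_boxcox_lambda
#' @param lambda power parameter.
#' @export
apply_boxcox <- function(x, lambda) {
  if (any(x <= 0, na.rm = TRUE))
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Tukey fencing with winsorization
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are clamped to the nearer fence;
#' all others are unchanged. Quartiles use linear interpolation of order
#' statistics (type 7). Idempotent; never changes rank order.
#'
#' @param x numeric vector, n >= 4.
#' @param k fence multiplier (default 3, "far out" fences).
#' @return list with `values` (adjusted vector) and `n_adjusted`.
#' @export
tukey_winsorize <- function(x, k = 3) {
  ok <- is.finite(x)
  q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
  out <- x
  n_adj <- sum(out[ok] < lo | out[ok] > hi)
  out[ok] <- pmin(pmax(out[ok], lo), hi)
  list(values = out, n_adjusted = n_adj, fences = c(lower = lo, upper = hi))
}

#' Standardize to the control distribution
#'
#' z = (x - mean(controls)) / SD(controls), so coefficients downstream are in
#' units of one control SD.
#'
#' @param x numeric vector.
#' @param control_mask logical vector marking control subjects.
#' @return list with `z`, `control_mean`, `control_sd`.
#' @export
standardize_to_controls <- function(x, control_mask) {
  cv <- x[control_mask & is.finite(x)]
  if (length(cv) < 2) stop("need >= 2 finite control values", call. = FALSE)
  s <- stats::sd(cv)
  if (s == 0) stop("zero control SD", call. = FALSE)
  list(z = (x - mean(cv)) / s, control_mean = mean(cv), control_sd = s)
}

#' Conditional-mean imputation of a covariate
#'
#' Missing entries are replaced by the mean of observed values in the same
#' (group, sex) cell; empty cells fall back to the group mean, then the grand
#' mean, with a warning.
#'
#' @param table data.frame.
#' @param column column name to impute.
#' @param condition_cols conditioning columns (default group and sex).
#' @return the table with `column` imputed.
#' @export
impute_conditional_mean <- function(table, column,
                                    condition_cols = c("group", "sex")) {
  x <- table[[column]]
  miss <- is.na(x)
  if (!any(miss)) return(table)
  key <- interaction(table[condition_cols], drop = FALSE)
  for (i in which(miss)) {
    cell <- x[key == key[i] & !miss]
    if (length(cell) == 0) {
      warning("empty (", paste(condition_cols, collapse = ","),
              ") cell; falling back", call. = FALSE)
      cell <- x[table[[condition_cols[1]]] == table[[condition_cols[1]]][i] & !miss]
      if (length(cell) == 0) cell <- x[!miss]
    }
    x[i] <- mean(cell)
  }
  table[[column]] <- x
  table
}

#' Half-minimum interpolation of non-detected values
#'
#' Missing values are set to half of the smallest detected value, the
#' convention used for analytes with occasional absent peaks.
#'
#' @param x numeric vector with NA for non-detected entries.
#' @return vector with NAs replaced.
#' @export
half_min_interpolate <- function(x) {
  det <- x[is.finite(x)]
  if (length(det) == 0) stop("no detected values to interpolate from", call. = FALSE)
  x[!is.finite(x)] <- min(det) / 2
  x
}

#' Filter rare SNPs
#'
#' Retains a SNP only if the alternate allele is present in at least
#' `min_carriers` subjects (carrier counting by default; allele counting as
#' an option).
#'
#' @param genotypes matrix subjects x SNPs of allele counts 0/1/2 (NA
#'   missing).
#' @param min_carriers minimum number of samples carrying the alternate
#'   allele.
#' @param mode "carriers" counts subjects with count >= 1; "alleles" counts
#'   total alternate alleles.
#' @return filtered genotype matrix.
#' @export
filter_rare_snps <- function(genotypes, min_carriers = 5,
                             mode = c("carriers", "alleles")) {
  mode <- match.arg(mode)
  cnt <- if (mode == "carriers")
    colSums(genotypes >= 1, na.rm = TRUE)
  else colSums(genotypes, na.rm = TRUE)
  genotypes[, cnt >= min_carriers, drop = FALSE]
}

#' Acute-levodopa exposure indicators from tissue DOPA
#'
#' A PD subject is flagged as acutely levodopa-exposed (L+) when log-DOPA
#' exceeds the parametric 95th percentile of the control distribution
#' (control mean + 1.6449 x control SD). The flag is routed into separate
#' indicator columns for demented (PD-D) and non-demented (PD-ND) PD, giving
#' the exposure-by-dementia interaction covariates.
#'
#' @param log_dopa numeric vector of log DOPA values.
#' @param group group labels.
#' @param pd_dem_groups groups treated as demented PD.
#' @param pd_nd_groups groups treated as non-demented PD.
#' @param control_group control label.
#' @return data.frame with integer columns `dopa_pdd` and `dopa_pdnd`, plus
#'   attribute `threshold`.
#' @export
derive_dopa_indicators <- function(log_dopa, group,
                                   pd_dem_groups = "PD-D",
                                   pd_nd_groups = c("PD-MCI", "PD-CN"),
                                   control_group = "HC-CN") {
  ctrl <- log_dopa[group == control_group & is.finite(log_dopa)]
  if (length(ctrl) < 2) stop("no controls to estimate the DOPA threshold",
                             call. = FALSE)
  thr <- mean(ctrl) + 1.6449 * stats::sd(ctrl)
  above <- is.finite(log_dopa) & log_dopa > thr
  out <- data.frame(
    dopa_pdd = as.integer(above & group %in% pd_dem_groups),
    dopa_pdnd = as.integer(above & group %in% pd_nd_groups)
  )
  attr(out, "threshold") <- thr
  out
}

#' Full preprocessing chain for a raw assay
#'
#' Per plate and metabolite: fits the quadratic calibration and inverts
#' sample signals to concentrations; computes blank-based LODs and flags
#' metabolites in the majority below LOD; estimates and applies Box-Cox per
#' metabolite (lambda profiled within group x plate cells); normalizes the
#' transformed values across plates respecting groups; adjusts remote
#' outliers by Tukey fencing (k = 3); and standardizes to the control
#' distribution.
#'
#' @param assay a [generate_raw_assay()] result (or a list with the same
#'   shape read from TSV).
#' @param subjects subject table with `subject_id` and `group`.
#' @param control_group control label for standardization.
#' @param tukey_k fence multiplier.
#' @param boxcox whether to apply the Box-Cox stage.
#' @return object of class `processed_matrix`: list with `z` (subjects x
#'   metabolites matrix of control-standardized values), `meta` (per
#'   metabolite: lambda, shift, control mean/SD, LODs, excluded flag,
#'   winsorized count), `plate` assignment and `excluded` metabolite names.
#' @export
preprocess_assay <- function(assay, subjects, control_group = "HC-CN",
                             tukey_k = 3, boxcox = TRUE) {
  wells <- assay$wells
  mets <- assay$panel$metabolite
  plate <- assay$plate_assignment[subjects$subject_id]
  n_plates <- max(plate)

  samp <- wells[wells$well_type == "sample", ]
  sig <- matrix(NA_real_, nrow(subjects), length(mets),
                dimnames = list(subjects$subject_id, mets))
  sig[cbind(match(samp$subject_id, subjects$subject_id),
            match(samp$metabolite, mets))] <- samp$signal

  conc <- sig
  lods <- matrix(NA_real_, n_plates, length(mets),
                 dimnames = list(NULL, mets))
  meta <- stats::setNames(vector("list", length(mets)), mets)
  for (m in mets) {
    cal_info <- vector("list", n_plates)
    for (pl in seq_len(n_plates)) {
      cal <- wells[wells$well_type == "calibrator" & wells$plate == pl &
                     wells$metabolite == m, ]
      curve <- if (nrow(cal) >= 3)
        fit_calibration(cal$known_conc, cal$signal)
      else suppressWarnings(fit_calibration(numeric(0), numeric(0)))
      sel <- plate == pl
      conc[sel, m] <- apply_calibration(curve, sig[sel, m])
      bl <- wells[wells$well_type == "blank" & wells$plate == pl &
                    wells$metabolite == m, "signal"]
      lods[pl, m] <- if (length(bl) >= 2) compute_lod(bl) else -Inf
      cal_info[[pl]] <- curve$type
    }
    meta[[m]] <- list(calibration = cal_info)
  }

  excluded <- flag_below_lod(sig, lods, plate)

  z <- matrix(NA_real_, nrow(subjects), length(mets),
              dimnames = list(subjects$subject_id, mets))
  ctrl_mask <- subjects$group == control_group
  # lambda is profiled within group x plate cells so that genuine location
  # differences (group effects, plate offsets) do not masquerade as skewness;
  # transforming before plate normalization keeps multiplicative plate
  # offsets additive on the transformed scale, where the normalization
  # removes them exactly
  cells <- interaction(subjects$group, plate, drop = TRUE)
  for (m in mets) {
    x <- conc[, m]
    shift <- 0
    if (boxcox) {
      if (min(x, na.rm = TRUE) <= 0) {
        shift <- 1 - min(x, na.rm = TRUE)
        x <- x + shift
      }
      lam <- estimate_boxcox_lambda(x, groups = cells)
      x <- apply_boxcox(x, lam)
    } else lam <- NA_real_
    x <- normalize_across_plates(x, plate, subjects$group)
    tw <- tukey_winsorize(x, k = tukey_k)
    x <- tw$values
    st <- standardize_to_controls(x, ctrl_mask)
    z[, m] <- st$z
    meta[[m]] <- c(meta[[m]], list(
      lambda = lam, shift = shift,
      control_mean = st$control_mean, control_sd = st$control_sd,
      lod = lods[, m], excluded = unname(excluded[m]),
      n_winsorized = tw$n_adjusted))
  }
  structure(list(z = z, meta = meta, plate = plate,
                 excluded = names(excluded)[excluded],
                 control_group = control_group),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat("Processed metabolite matrix:", nrow(x$z), "subjects x",
      ncol(x$z), "metabolites\n")
  if (length(x$excluded))
    cat("Excluded (majority below LOD):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
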