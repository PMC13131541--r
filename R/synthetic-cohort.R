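#' Cohort configuration for the synthetic study generator
#'
#' Bundles group sizes, per-group covariate distributions and the fraction of
#' Parkinson's disease (PD) subjects with acute levodopa exposure at death.
#' Defaults emulate a post-mortem brain-bank case-control cohort: healthy
#' cognitively-normal controls (HC-CN), PD subjects split by cognitive status
#' (PD-CN, PD-MCI, PD-D) and Alzheimer's dementia (AD-D), with short
#' post-mortem intervals and decade-scale freezer storage.
#'
#' @param group_sizes named integer vector, subjects per group. Defaults to
#'   the cortex cohort layout: 36 HC-CN, 14 PD-CN, 19 PD-MCI, 32 PD-D, 35 AD-D
#'   (n = 136).
#' @param covariate_params named list of per-group covariate distributions;
#'   see [default_covariate_params()]. Groups missing from the list fall back
#'   to the defaults.
#' @param levodopa_fraction fraction of PD subjects (groups starting "PD")
#'   with acute levodopa exposure at death.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("HC-CN" = 36, "PD-CN" = 14,
                                          "PD-MCI" = 19, "PD-D" = 32,
                                          "AD-D" = 35),
                          covariate_params = default_covariate_params(),
                          levodopa_fraction = 0.5,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector", call. = FALSE)
  if (any(group_sizes < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (levodopa_fraction < 0 || levodopa_fraction > 1)
    stop("levodopa_fraction must be in [0, 1]", call. = FALSE)
  structure(list(group_sizes = group_sizes,
                 covariate_params = covariate_params,
                 levodopa_fraction = levodopa_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-group covariate distributions
#'
#' Age, education and BMI are Gaussian; sex and comorbidities Bernoulli;
#' post-mortem interval (hours) log-normal around a short brain-bank interval;
#' storage years uniform. Values are chosen to resemble an elderly autopsy
#' cohort with balanced sociodemographics across groups.
#'
#' @return named list: one entry per group, each a list of distribution
#'   parameters.
#' @export
default_covariate_params <- function() {
  base <- list(
    age_mean = 81, age_sd = 6,
    female_prop = 0.45,
    edu_mean = 15, edu_sd = 2.5,
    bmi_mean = 25.5, bmi_sd = 4,
    hyperlipidemia = 0.45, diabetes = 0.12,
    renal_insufficiency = 0.08, hypothyroidism = 0.15,
    supplement_prob = 0.35,
    pmi_meanlog = 1.15, pmi_sdlog = 0.35,   # ~3.2 h median
    storage_min = 4, storage_max = 18
  )
  list("HC-CN" = base, "PD-CN" = base, "PD-MCI" = base,
       "PD-D" = base, "AD-D" = base, ".default" = base)
}

#' Generate a synthetic subject table
#'
#' Draws one row per subject with group label, demographics, comorbidity
#' flags, supplementation flag, post-mortem interval (hours), freezer storage
#' (years) and — for PD groups — an acute-levodopa exposure flag.
#'
#' @param config a [cohort_config()] object.
#' @return `data.frame` with one row per subject.
#' @export
generate_subjects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cp <- config$covariate_params
  rng <- local_rng(config$seed)
  rows <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0) return(NULL)
    p <- cp[[g]]
    if (is.null(p)) p <- cp[[".default"]]
    if (is.null(p)) stop("unknown group label with no defaults: ", g, call. = FALSE)
    data.frame(
      subject_id = character(n),
      group = g,
      sex = ifelse(stats::runif(n) < p$female_prop, "F", "M"),
      age = round(stats::rnorm(n, p$age_mean, p$age_sd), 1),
      education = pmax(6, round(stats::rnorm(n, p$edu_mean, p$edu_sd))),
      bmi = round(pmax(15, stats::rnorm(n, p$bmi_mean, p$bmi_sd)), 1),
      hyperlipidemia = as.integer(stats::runif(n) < p$hyperlipidemia),
      diabetes = as.integer(stats::runif(n) < p$diabetes),
      renal_insufficiency = as.integer(stats::runif(n) < p$renal_insufficiency),
      hypothyroidism = as.integer(stats::runif(n) < p$hypothyroidism),
      supplementation = as.integer(stats::runif(n) < p$supplement_prob),
      pmi_hours = round(stats::rlnorm(n, p$pmi_meanlog, p$pmi_sdlog), 2),
      storage_years = round(stats::runif(n, p$storage_min, p$storage_max), 1),
      levodopa_exposed = if (startsWith(g, "PD"))
        as.integer(stats::runif(n) < config$levodopa_fraction) else 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), group = character(0))
  } else {
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    rownames(out) <- NULL
  }
  rng()  # restore RNG state
  out
}

#' Effect specification for planted metabolite group differences
#'
#' @param metabolite panel metabolite name.
#' @param group group label the effect applies to.
#' @param effect signed effect in control-SD units of the log concentration.
#' @param levodopa_only if TRUE the effect applies only to levodopa-exposed
#'   subjects of the group (an exposure interaction).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(metabolite, group, effect, levodopa_only = FALSE) {
  structure(list(metabolite = metabolite, group = group,
                 effect = effect, levodopa_only = isTRUE(levodopa_only)),
            class = "effect_spec")
}

#' Default metabolite panel
#'
#' Log-scale baseline means (arbitrary signal units) and control-level
#' biological SDs for a one-carbon-metabolism panel: homocysteine, betaine,
#' B-vitamin actives and markers, and tissue DOPA.
#' @return data.frame with columns metabolite, log_mean, log_sd.
#' @export
default_panel <- function() {
  data.frame(
    metabolite = c("Hcy", "betaine", "biotin", "THF", "MTHF", "PLP",
                   "TMP", "TPP", "pantothenate", "nicotinamide", "MMA", "DOPA"),
    log_mean = c(4.5, 6.0, 3.2, 3.8, 4.1, 5.0, 4.4, 5.6, 6.2, 5.2, 3.0, 2.0),
    log_sd = c(0.45, 0.40, 0.50, 0.55, 0.50, 0.45, 0.40, 0.35, 0.40,
               0.45, 0.50, 0.60),
    stringsAsFactors = FALSE
  )
}

#' Generate raw per-plate assay tables
#'
#' Simulates instrument signals at the peak-area level. Sample concentrations
#' are log-normal: log C = baseline + planted group effect (in control-SD
#' units) + plate offset + biological noise. Each plate carries blank wells
#' (for limit-of-detection estimation), QC replicates and calibrator wells on
#' a known quadratic response. Levodopa-exposed PD subjects get elevated
#' log-DOPA. Optionally, genotype-driven effects shift metabolite levels.
#'
#' @param subjects a subject table from [generate_subjects()].
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param panel metabolite panel; default [default_panel()].
#' @param n_plates number of plates; subjects are assigned stratified by
#'   group by default.
#' @param plate_offset_sd SD of per-plate additive log-scale offsets.
#' @param stratified stratify plate assignment by group (default TRUE).
#' @param genotypes optional genotype matrix (subjects x SNPs, values 0/1/2)
#'   used with `snp_effects`.
#' @param snp_effects optional list of lists with fields `snp`, `metabolite`,
#'   `effect` (per-allele shift in control-SD units, additive coding).
#' @param dopa_shift log-scale elevation of DOPA for levodopa-exposed
#'   subjects, in units of the DOPA control SD.
#' @param n_blanks,n_qc,n_calibrators wells per plate of each type.
#' @param calibrator_noise_sd Gaussian signal noise on calibrator wells
#'   (default 0: calibrators sit exactly on the response curve).
#' @param seed integer seed.
#' @return list of class `raw_assay` with elements `wells` (long data.frame:
#'   plate, well_type, subject_id, metabolite, signal, known_conc),
#'   `plate_assignment`, `panel`, and `response` (quadratic response
#'   coefficients per metabolite).
#' @export
generate_raw_assay <- function(subjects, effects = list(),
                               panel = default_panel(),
                               n_plates = 2, plate_offset_sd = 0.15,
                               stratified = TRUE,
                               genotypes = NULL, snp_effects = NULL,
                               dopa_shift = 3,
                               n_blanks = 3, n_qc = 3, n_calibrators = 7,
                               calibrator_noise_sd = 0,
                               seed = 1L) {
  for (e in effects) {
    if (!e$metabolite %in% panel$metabolite)
      stop("effect on unknown metabolite: ", e$metabolite, call. = FALSE)
    if (!e$group %in% subjects$group)
      stop("effect on group absent from cohort: ", e$group, call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(subjects)

  # plate assignment, stratified by group so plate effects do not confound
  plate <- integer(n)
  if (stratified) {
    for (g in unique(subjects$group)) {
      idx <- which(subjects$group == g)
      idx <- sample(idx)
      plate[idx] <- rep_len(seq_len(n_plates), length(idx))
    }
  } else {
    plate <- sample(rep_len(seq_len(n_plates), n))
  }

  plate_offsets <- matrix(stats::rnorm(n_plates * nrow(panel), 0, plate_offset_sd),
                          nrow = n_plates,
                          dimnames = list(NULL, panel$metabolite))

  # quadratic instrument response per metabolite: signal = a + b*C + c*C^2
  resp <- data.frame(metabolite = panel$metabolite,
                     a = 2, b = 1, c = 1e-4,
                     stringsAsFactors = FALSE)

  wells <- vector("list", 4L)

  # sample wells
  logc <- matrix(rep(panel$log_mean, each = n), nrow = n,
                 dimnames = list(subjects$subject_id, panel$metabolite))
  sds <- stats::setNames(panel$log_sd, panel$metabolite)
  for (m in panel$metabolite)
    logc[, m] <- logc[, m] + stats::rnorm(n, 0, sds[m])
  for (e in effects) {
    sel <- subjects$group == e$group
    if (e$levodopa_only) sel <- sel & subjects$levodopa_exposed == 1L
    logc[sel, e$metabolite] <- logc[sel, e$metabolite] + e$effect * sds[e$metabolite]
  }
  if (!is.null(snp_effects)) {
    if (is.null(genotypes)) stop("snp_effects requires genotypes", call. = FALSE)
    for (se in snp_effects) {
      g <- genotypes[subjects$subject_id, se$snp]
      g[is.na(g)] <- 0
      logc[, se$metabolite] <- logc[, se$metabolite] + se$effect * sds[se$metabolite] * g
    }
  }
  if ("DOPA" %in% panel$metabolite && any(subjects$levodopa_exposed == 1L)) {
    sel <- subjects$levodopa_exposed == 1L
    logc[sel, "DOPA"] <- logc[sel, "DOPA"] + dopa_shift * sds["DOPA"]
  }
  for (m in panel$metabolite)
    logc[, m] <- logc[, m] + plate_offsets[plate, m]
  conc <- exp(logc)
  rcoef <- resp[match(panel$metabolite, resp$metabolite), ]
  sig <- sweep(sweep(conc^2, 2, rcoef$c, `*`) + sweep(conc, 2, rcoef$b, `*`),
               2, rcoef$a, `+`)
  wells[[1L]] <- data.frame(
    plate = rep(plate, times = nrow(panel)),
    well_type = "sample",
    subject_id = rep(subjects$subject_id, times = nrow(panel)),
    metabolite = rep(panel$metabolite, each = n),
    signal = as.vector(sig),
    known_conc = NA_real_,
    stringsAsFactors = FALSE
  )

  # blanks, QC, calibrators per plate x metabolite
  blank_mu <- 3; blank_sd <- 0.5
  per_plate <- lapply(seq_len(n_plates), function(pl) {
    bl <- expand.grid(metabolite = panel$metabolite, w = seq_len(n_blanks),
                      stringsAsFactors = FALSE)
    bl <- data.frame(plate = pl, well_type = "blank", subject_id = NA_character_,
                     metabolite = bl$metabolite,
                     signal = abs(stats::rnorm(nrow(bl), blank_mu, blank_sd)),
                     known_conc = NA_real_, stringsAsFactors = FALSE)
    qc_conc <- exp(panel$log_mean)
    qc <- expand.grid(mi = seq_len(nrow(panel)), w = seq_len(n_qc))
    qc_c <- qc_conc[qc$mi] * exp(stats::rnorm(nrow(qc), 0, 0.03))
    qc <- data.frame(plate = pl, well_type = "qc", subject_id = NA_character_,
                     metabolite = panel$metabolite[qc$mi],
                     signal = rcoef$a[qc$mi] + rcoef$b[qc$mi] * qc_c +
                       rcoef$c[qc$mi] * qc_c^2,
                     known_conc = NA_real_, stringsAsFactors = FALSE)
    cal <- expand.grid(mi = seq_len(nrow(panel)), w = seq_len(n_calibrators))
    # geometric calibrator series spanning the sample range
    cal_conc <- exp(panel$log_mean[cal$mi] +
                      (cal$w - (n_calibrators + 1) / 2) * 0.6)
    cal_sig <- rcoef$a[cal$mi] + rcoef$b[cal$mi] * cal_conc +
      rcoef$c[cal$mi] * cal_conc^2
    if (calibrator_noise_sd > 0)
      cal_sig <- cal_sig + stats::rnorm(nrow(cal), 0, calibrator_noise_sd)
    cal <- data.frame(plate = pl, well_type = "calibrator",
                      subject_id = NA_character_,
                      metabolite = panel$metabolite[cal$mi],
                      signal = cal_sig, known_conc = cal_conc,
                      stringsAsFactors = FALSE)
    rbind(bl, qc, cal)
  })
  wells[[2L]] <- do.call(rbind, per_plate)
  out <- rbind(wells[[1L]], wells[[2L]])
  rownames(out) <- NULL
  structure(list(wells = out,
                 plate_assignment = stats::setNames(plate, subjects$subject_id),
                 panel = panel, response = resp),
            class = "raw_assay")
}

#' SNP specification for the genotype simulator
#'
#' @param snp_id identifier (e.g. an rs number).
#' @param maf minor-allele frequency in (0, 0.5].
#' @param inheritance one of "dominant", "recessive", "additive" (used by
#'   downstream planted-effect helpers, not by genotype sampling).
#' @param group_odds optional named vector of per-group odds multipliers on
#'   the allele frequency (allele enrichment by group).
#' @return list of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, maf, inheritance = "additive", group_odds = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]", call. = FALSE)
  inheritance <- match.arg(inheritance, c("dominant", "recessive", "additive"))
  structure(list(snp_id = snp_id, maf = maf, inheritance = inheritance,
                 group_odds = group_odds), class = "snp_spec")
}

#' Linkage-disequilibrium specification for a SNP pair
#'
#' @param snp_pair character vector of two SNP ids.
#' @param target_dprime absolute D' to plant, in `[0, 1]`.
#' @param phase "coupling" (minor alleles co-occur) or "repulsion" (minor
#'   alleles avoid each other; at D' = 1 the double-minor haplotype is absent).
#' @return list of class `ld_spec`.
#' @export
ld_spec <- function(snp_pair, target_dprime, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  if (target_dprime < 0 || target_dprime > 1)
    stop("target_dprime must be in [0, 1]", call. = FALSE)
  structure(list(snp_pair = snp_pair, target_dprime = target_dprime,
                 phase = phase), class = "ld_spec")
}

# Solve the 4 haplotype frequencies from two allele frequencies and D'.
# Alleles coded 1 = minor. D = p11 - pA*pB; D' = D / Dmax with the
# sign-appropriate bound. Returns c(p11, p10, p01, p00).
haplotype_pool <- function(pA, pB, dprime, phase) {
  if (phase == "coupling") {
    dmax <- min(pA * (1 - pB), pB * (1 - pA))
    D <- dprime * dmax
  } else {
    dmax <- min(pA * pB, (1 - pA) * (1 - pB))
    D <- -dprime * dmax
  }
  h <- c(p11 = pA * pB + D, p10 = pA * (1 - pB) - D,
         p01 = (1 - pA) * pB - D, p00 = (1 - pA) * (1 - pB) + D)
  if (any(h < -1e-12))
    stop("LD target unreachable at the given allele frequencies", call. = FALSE)
  pmax(h, 0)
}

#' Generate a synthetic genotype matrix
#'
#' SNPs not involved in an LD pair are sampled under Hardy-Weinberg
#' equilibrium at the stated minor-allele frequency (optionally with per-group
#' allele-frequency enrichment). LD pairs are sampled by explicit haplotype
#' pools: the four haplotype frequencies are solved from the two MAFs and the
#' target D', and each subject draws two haplotypes.
#'
#' @param subjects subject table.
#' @param snp_specs list of [snp_spec()] objects.
#' @param ld_specs list of [ld_spec()] objects (SNPs must appear in
#'   `snp_specs`).
#' @param missing_rate optional MCAR genotype missingness rate.
#' @param seed integer seed.
#' @return integer matrix subjects x SNPs with allele counts 0/1/2 (NA for
#'   missing).
#' @export
generate_genotypes <- function(subjects, snp_specs, ld_specs = list(),
                               missing_rate = 0, seed = 1L) {
  ids <- vapply(snp_specs, function(s) s$snp_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate snp ids", call. = FALSE)
  for (l in ld_specs)
    if (!all(l$snp_pair %in% ids))
      stop("ld_spec references undeclared SNP", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(subjects)
  G <- matrix(NA_integer_, n, length(ids),
              dimnames = list(subjects$subject_id, ids))
  in_ld <- unique(unlist(lapply(ld_specs, `[[`, "snp_pair")))
  specs <- stats::setNames(snp_specs, ids)

  for (s in snp_specs) {
    if (s$snp_id %in% in_ld) next
    maf <- rep(s$maf, n)
    if (!is.null(s$group_odds)) {
      for (g in names(s$group_odds)) {
        sel <- subjects$group == g
        odds <- s$maf / (1 - s$maf) * s$group_odds[[g]]
        maf[sel] <- odds / (1 + odds)
      }
    }
    G[, s$snp_id] <- stats::rbinom(n, 2L, maf)
  }
  for (l in ld_specs) {
    pA <- specs[[l$snp_pair[1]]]$maf
    pB <- specs[[l$snp_pair[2]]]$maf
    h <- haplotype_pool(pA, pB, l$target_dprime, l$phase)
    # two haplotype draws per subject; haplotype k -> allele pair
    alle <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
    d1 <- sample.int(4L, n, replace = TRUE, prob = h)
    d2 <- sample.int(4L, n, replace = TRUE, prob = h)
    G[, l$snp_pair[1]] <- alle[d1, 1L] + alle[d2, 1L]
    G[, l$snp_pair[2]] <- alle[d1, 2L] + alle[d2, 2L]
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(G)) < missing_rate, nrow(G))
    G[mask] <- NA_integer_
  }
  G
}

#' Plant a binary classification rule over cohort features
#'
#' Evaluates a logical expression over the columns of `data` and flips the
#' result with a given noise rate, producing a planted two-class label for
#' classifier-recovery experiments.
#'
#' @param data data.frame of subject-level features (e.g. metabolite z-scores
#'   and genotype columns).
#' @param rule one-sided formula or quoted expression evaluating to logical
#'   in the context of `data`, e.g. `~ snpA == 0 & snpB == 0`.
#' @param noise_rate probability of flipping each label.
#' @param seed integer seed.
#' @return integer vector of 0/1 labels.
#' @export
plant_classification_rule <- function(data, rule, noise_rate = 0, seed = 1L) {
  expr <- if (inherits(rule, "formula")) rule[[2L]] else rule
  lab <- eval(expr, envir = data, enclos = parent.frame())
  if (!is.logical(lab) && !all(lab %in% c(0, 1)))
    stop("rule must evaluate to a logical vector", call. = FALSE)
  if (anyNA(lab)) stop("rule references missing feature values", call. = FALSE)
  lab <- as.integer(lab)
  if (noise_rate > 0) {
    rng <- local_rng(seed)
    on.exit(rng())
    flip <- stats::runif(length(lab)) < noise_rate
    lab[flip] <- 1L - lab[flip]
  }
  lab
}

# Seed the RNG locally and return a restorer callback.
local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}
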