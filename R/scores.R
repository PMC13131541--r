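#' Build the composite-score risk and protection sets
#'
#' From the SNP association tables (homocysteine and betaine responses, with
#' chosen inheritance models and direction labels) and the vitamin
#' association tables: SNPs significantly associated with elevated Hcy or
#' decreased betaine form the risk set; the converse directions the
#' protection set; vitamins significantly negatively associated with Hcy or
#' positively with betaine form the vitamin set. A SNP appearing for both
#' responses in a consistent direction is counted once; a SNP with
#' conflicting directions is dropped from both sets with a warning.
#'
#' @param snp_assoc data.frame from [snp_metabolite_assoc()] (rows for both
#'   responses may be concatenated).
#' @param vitamin_assoc data.frame from [run_covariate_assoc()] with a
#'   `response` column ("hcy"/"betaine") and `term` = vitamin.
#' @param snp_q_threshold significance threshold for SNP q-values
#'   (genomic analysis: 0.1).
#' @param vitamin_fdr_threshold threshold for vitamin FDR (metabolomic
#'   analysis: 0.05).
#' @param z_threshold low-level cut for the vitamin risk score (the
#'   parametric 5th percentile of the control distribution, -1.6449,
#'   conventionally displayed as -1.64).
#' @return object of class `risk_sets`: `snp_risk` and `snp_protect`
#'   (data.frames snp + model), `vitamins` (character), `z_threshold`.
#' @export
build_risk_sets <- function(snp_assoc, vitamin_assoc,
                            snp_q_threshold = 0.1,
                            vitamin_fdr_threshold = 0.05,
                            z_threshold = -1.6449) {
  if (nrow(snp_assoc) == 0 && nrow(vitamin_assoc) == 0)
    warning("empty association tables; all sets empty", call. = FALSE)
  sig <- snp_assoc[!is.na(snp_assoc$q) & snp_assoc$q <= snp_q_threshold, ,
                   drop = FALSE]
  pick <- function(dir) {
    s <- sig[sig$direction == dir, c("snp", "model"), drop = FALSE]
    s[!duplicated(s$snp), , drop = FALSE]
  }
  risk <- pick("risk"); protect <- pick("protective")
  both <- intersect(risk$snp, protect$snp)
  if (length(both)) {
    warning("SNPs with conflicting directions dropped: ",
            paste(both, collapse = ", "), call. = FALSE)
    risk <- risk[!risk$snp %in% both, , drop = FALSE]
    protect <- protect[!protect$snp %in% both, , drop = FALSE]
  }
  vit <- character(0)
  if (nrow(vitamin_assoc)) {
    va <- vitamin_assoc[!is.na(vitamin_assoc$fdr) &
                          vitamin_assoc$fdr <= vitamin_fdr_threshold, ,
                        drop = FALSE]
    keep <- (va$response == "hcy" & va$beta < 0) |
      (va$response == "betaine" & va$beta > 0)
    vit <- unique(va$term[keep])
  }
  structure(list(snp_risk = risk, snp_protect = protect,
                 vitamins = vit, z_threshold = z_threshold),
            class = "risk_sets")
}

#' @export
print.risk_sets <- function(x, ...) {
  cat("Composite-score sets: ", nrow(x$snp_risk), " risk SNPs, ",
      nrow(x$snp_protect), " protective SNPs, ",
      length(x$vitamins), " vitamins (z < ",
      sprintf("%.2f", x$z_threshold), ")\n", sep = "")
  invisible(x)
}

# Does a genotype meet the criterion of its chosen inheritance model?
# additive contributes the allele count in "allele" mode, carrier status in
# "carrier" mode.
snp_criterion <- function(g, model, additive_mode) {
  switch(model,
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2),
         additive = if (additive_mode == "allele") as.numeric(g)
                    else as.numeric(g >= 1),
         stop("unknown model: ", model, call. = FALSE))
}

#' SNP burden score per subject
#'
#' Counts, over the SNPs of a risk or protection set, how many criteria the
#' subject meets under each SNP's chosen inheritance model (dominant:
#' carrier; recessive: homozygote; additive: carrier by default, allele
#' count in "allele" mode). Missing genotypes are handled by scoring the
#' observed set members and rescaling to the full set size, so missingness
#' does not deflate the score (the result can then be fractional).
#'
#' @param genotypes matrix subjects x SNPs.
#' @param set data.frame with columns `snp`, `model` (a component of
#'   [build_risk_sets()] output).
#' @param additive_mode "carrier" or "allele".
#' @return numeric vector of scores (length = subjects).
#' @export
snp_score <- function(genotypes, set, additive_mode = c("carrier", "allele")) {
  additive_mode <- match.arg(additive_mode)
  n <- nrow(genotypes)
  if (nrow(set) == 0) return(rep(0, n))
  contrib <- matrix(NA_real_, n, nrow(set))
  for (j in seq_len(nrow(set))) {
    g <- genotypes[, set$snp[j]]
    obs <- !is.na(g)
    contrib[obs, j] <- snp_criterion(g[obs], set$model[j], additive_mode)
  }
  n_obs <- rowSums(!is.na(contrib))
  raw <- rowSums(contrib, na.rm = TRUE)
  ifelse(n_obs > 0, raw * nrow(set) / n_obs, 0)
}

#' B-vitamin risk score per subject
#'
#' Counts how many set vitamins fall below the control 5th-percentile
#' threshold (z < -1.6449 by default).
#'
#' @param z matrix subjects x metabolites of control-standardized values.
#' @param vitamins character vector of set members.
#' @param threshold z cut-off.
#' @return integer vector of scores.
#' @export
vitamin_risk_score <- function(z, vitamins, threshold = -1.6449) {
  if (length(vitamins) == 0) return(rep(0L, nrow(z)))
  rowSums(z[, vitamins, drop = FALSE] < threshold, na.rm = TRUE)
}

#' Compute the three composite scores for a cohort
#'
#' @param genotypes matrix subjects x SNPs.
#' @param z processed metabolite matrix (subjects x metabolites).
#' @param sets a [build_risk_sets()] object.
#' @param additive_mode see [snp_score()].
#' @return data.frame: subject_id, snp_risk (A), snp_protect (B),
#'   vitamin_risk (C).
#' @export
composite_scores <- function(genotypes, z, sets,
                             additive_mode = c("carrier", "allele")) {
  additive_mode <- match.arg(additive_mode)
  data.frame(
    subject_id = rownames(genotypes),
    snp_risk = snp_score(genotypes, sets$snp_risk, additive_mode),
    snp_protect = snp_score(genotypes, sets$snp_protect, additive_mode),
    vitamin_risk = vitamin_risk_score(z, sets$vitamins, sets$z_threshold),
    stringsAsFactors = FALSE
  )
}

#' Compare composite scores of each group against controls
#'
#' Per group: mean score, percent difference from the control mean
#' (Delta% = 100 (mean_g - mean_c) / mean_c) and a two-sided
#' Wilcoxon-Mann-Whitney p-value. A zero control mean makes Delta%
#' undefined; the absolute difference is reported instead with a flag.
#'
#' @param scores numeric vector of per-subject scores.
#' @param groups group labels.
#' @param control_group reference label.
#' @return data.frame: group, n, mean, delta_pct, p, absolute_flag.
#' @export
compare_to_controls <- function(scores, groups, control_group = "HC-CN") {
  if (!control_group %in% groups) stop("control group absent", call. = FALSE)
  ctrl <- scores[groups == control_group]
  mc <- mean(ctrl)
  rows <- lapply(setdiff(unique(groups), control_group), function(g) {
    sg <- scores[groups == g]
    res <- wmw_group_test(sg, ctrl)
    if (mc != 0) {
      data.frame(group = g, n = length(sg), mean = mean(sg),
                 delta_pct = 100 * (mean(sg) - mc) / mc, p = res$p,
                 absolute_flag = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, n = length(sg), mean = mean(sg),
                 delta_pct = mean(sg) - mc, p = res$p,
                 absolute_flag = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
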