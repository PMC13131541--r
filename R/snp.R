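#' Wilcoxon-Mann-Whitney test for genotype distributions
#'
#' Rank-sum test of allele counts between two subject sets. For combined
#' sample sizes up to 16 the exact permutation distribution is enumerated
#' (all assignments of subjects to the two sets); otherwise a tie- and
#' continuity-corrected normal approximation to the rank-sum statistic is
#' used. All-tied data give p = 1.
#'
#' @param a,b numeric vectors (typically allele counts 0/1/2).
#' @param exact_max largest combined n for exact enumeration.
#' @return list with `p` (two-sided), `statistic` (rank sum of `a`) and
#'   `method`.
#' @export
wmw_group_test <- function(a, b, exact_max = 16) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b); n <- na + nb
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  if (length(unique(pooled)) == 1)
    return(list(p = 1, statistic = W, method = "degenerate"))
  mu <- na * (n + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, na)
    Ws <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    return(list(p = p, statistic = W, method = "exact"))
  }
  ties <- table(pooled)
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tiecor)
  z <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)  # continuity-corrected
  list(p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       statistic = W, method = "asymptotic")
}

#' Genotype frequency summary
#'
#' Percent heterozygous and homozygous-mutant subjects.
#' @param g allele counts 0/1/2.
#' @return named numeric: het_pct, hm_pct.
#' @export
genotype_freqs <- function(g) {
  g <- g[!is.na(g)]
  c(het_pct = 100 * mean(g == 1), hm_pct = 100 * mean(g == 2))
}

#' SNP differential-presence scan across subject subgroups
#'
#' For each SNP and each requested pairwise comparison of subject sets, a
#' Wilcoxon-Mann-Whitney test on allele counts, with q-values computed
#' across the whole scan (falls back to BH for small families), plus
#' per-group heterozygote/homozygote frequency summaries.
#'
#' @param genotypes matrix subjects x SNPs (rare SNPs already filtered).
#' @param groups group label per subject (row order of `genotypes`).
#' @param comparisons list of 2-element vectors of group labels; each entry
#'   may also be a list of two character vectors (pooled sets).
#' @return data.frame: snp, comparison, p, q, and het/hm percentages for
#'   both sides.
#' @export
snp_subgroup_scan <- function(genotypes, groups, comparisons) {
  rows <- list()
  for (cmp in comparisons) {
    ga <- if (is.list(cmp)) cmp[[1]] else cmp[1]
    gb <- if (is.list(cmp)) cmp[[2]] else cmp[2]
    sel_a <- groups %in% ga; sel_b <- groups %in% gb
    lab <- paste(paste(ga, collapse = "+"), "vs", paste(gb, collapse = "+"))
    if (!any(sel_a) || !any(sel_b)) {
      warning("empty comparison group; skipped: ", lab, call. = FALSE)
      next
    }
    for (s in colnames(genotypes)) {
      res <- wmw_group_test(genotypes[sel_a, s], genotypes[sel_b, s])
      fa <- genotype_freqs(genotypes[sel_a, s])
      fb <- genotype_freqs(genotypes[sel_b, s])
      rows[[length(rows) + 1L]] <- data.frame(
        snp = s, comparison = lab, p = res$p,
        het_pct_a = fa[["het_pct"]], hm_pct_a = fa[["hm_pct"]],
        het_pct_b = fb[["het_pct"]], hm_pct_b = fb[["hm_pct"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- if (nrow(out) >= 20) storey_qvalues(out$p)$qvalues
           else suppressWarnings(storey_qvalues(out$p)$qvalues)
  out
}

#' Inheritance-model selection for a SNP by BIC
#'
#' Fits three linear models of the response on the SNP coded as dominant
#' (carrier indicator, g >= 1), recessive (homozygote indicator, g == 2) and
#' additive (allele count), each adjusted for the tissue covariates, and
#' selects the model with minimum BIC. All three codings spend one
#' parameter, so BIC selection reduces to likelihood comparison. Ties prefer
#' additive, then dominant. The recessive model is dropped when no
#' homozygote is present.
#'
#' @param g allele counts 0/1/2.
#' @param y numeric response (e.g. transformed homocysteine).
#' @param covariates data.frame of adjustment covariates (sex, age, log PMI,
#'   log storage), or NULL for unadjusted fits.
#' @return object of class `inheritance_fit`: chosen model, per-model BIC,
#'   and beta/se/p of the chosen SNP term.
#' @export
choose_inheritance_model <- function(g, y, covariates = NULL) {
  ok <- !is.na(g) & !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  g <- g[ok]; y <- y[ok]
  covs <- if (!is.null(covariates)) covariates[ok, , drop = FALSE] else NULL
  if (stats::var(y) == 0) {
    # constant response: every coding fits identically; tie goes to additive
    return(structure(list(model = "additive",
                          bic = c(dominant = 0, recessive = 0, additive = 0),
                          beta = 0, se = NA_real_, p = 1, n = length(y)),
                     class = "inheritance_fit"))
  }
  codings <- list(dominant = as.numeric(g >= 1),
                  recessive = as.numeric(g == 2),
                  additive = as.numeric(g))
  if (length(unique(codings$recessive)) < 2) codings$recessive <- NULL
  codings <- Filter(function(x) length(unique(x)) > 1, codings)
  if (length(codings) == 0) stop("SNP has no genotype variation", call. = FALSE)
  fits <- lapply(codings, function(x) {
    d <- data.frame(.y = y, .g = x)
    if (!is.null(covs)) d <- cbind(d, covs)
    stats::lm(.y ~ ., data = d)
  })
  bic <- vapply(fits, stats::BIC, numeric(1))
  pref <- c("additive", "dominant", "recessive")
  cand <- names(bic)[bic <= min(bic) + 1e-9]
  chosen <- pref[pref %in% cand][1]
  sm <- summary(fits[[chosen]])$coefficients
  structure(list(model = chosen, bic = bic,
                 beta = sm[".g", "Estimate"], se = sm[".g", "Std. Error"],
                 p = sm[".g", "Pr(>|t|)"], n = length(y)),
            class = "inheritance_fit")
}

#' @export
print.inheritance_fit <- function(x, ...) {
  cat("Inheritance model:", x$model,
      sprintf("(beta = %.3f, p = %.3g, n = %d)\n", x$beta, x$p, x$n))
  cat("BIC:", paste(sprintf("%s %.2f", names(x$bic), x$bic), collapse = ", "),
      "\n")
  invisible(x)
}

#' SNP-metabolite association with per-SNP inheritance model
#'
#' For each SNP: selects the inheritance model by BIC against the response
#' and reports the chosen-model effect with q-values across SNPs, plus a
#' direction label for composite scores. For a homocysteine response a
#' positive effect is "risk" (raises Hcy); for betaine a negative effect is
#' "risk"; the converse directions are "protective".
#'
#' @param genotypes matrix subjects x SNPs.
#' @param y response vector aligned with rows.
#' @param covariates data.frame of tissue covariates (or NULL).
#' @param exclude_mask logical; subjects dropped from this analysis
#'   (acute-levodopa samples, whose homocysteine/betaine are perturbed).
#' @param response_type "hcy" or "betaine" (controls risk direction).
#' @return data.frame: snp, model, beta, se, p, q, direction.
#' @export
snp_metabolite_assoc <- function(genotypes, y, covariates = NULL,
                                 exclude_mask = NULL,
                                 response_type = c("hcy", "betaine")) {
  response_type <- match.arg(response_type)
  keep <- if (is.null(exclude_mask)) rep(TRUE, length(y)) else !exclude_mask
  rows <- lapply(colnames(genotypes), function(s) {
    fit <- choose_inheritance_model(genotypes[keep, s], y[keep],
                                    if (is.null(covariates)) NULL
                                    else covariates[keep, , drop = FALSE])
    data.frame(snp = s, model = fit$model, beta = fit$beta, se = fit$se,
               p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- suppressWarnings(storey_qvalues(out$p)$qvalues)
  risk_pos <- response_type == "hcy"  # raising Hcy is risk; raising betaine protects
  out$direction <- ifelse(out$beta > 0,
                          if (risk_pos) "risk" else "protective",
                          if (risk_pos) "protective" else "risk")
  out$response <- response_type
  out
}
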