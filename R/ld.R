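#' EM haplotype-frequency estimation for two unphased biallelic loci
#'
#' Maximum-likelihood estimation of the four two-locus haplotype frequencies
#' from unphased genotypes. Only the double-heterozygote class is phase
#' ambiguous; the EM step splits it between the coupling (AB/ab) and
#' repulsion (Ab/aB) resolutions in proportion to the current haplotype
#' frequency products. With no double heterozygotes EM coincides with direct
#' haplotype counting.
#'
#' @param g1,g2 allele counts 0/1/2 at the two loci; pairs with missing
#'   values are dropped.
#' @param tol convergence tolerance on the largest frequency change.
#' @param max_iter maximum EM iterations.
#' @return list with `freq` (named: p11, p10, p01, p00 — first index locus 1
#'   minor allele), `n` (informative subjects), `iterations`, `loglik`.
#' @export
estimate_haplotypes_em <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 5) stop("need >= 5 informative subjects", call. = FALSE)

  # known haplotype counts from unambiguous genotype classes
  # haplotypes: 1 = "11", 2 = "10", 3 = "01", 4 = "00" (minor-allele coding)
  base <- numeric(4)
  ndh <- 0L
  for (i in seq_len(n)) {
    a <- g1[i]; b <- g2[i]
    if (a == 1 && b == 1) { ndh <- ndh + 1L; next }
    # each genotype decomposes into two haplotypes deterministically
    h1a <- if (a >= 1) 1L else 0L; h2a <- if (a == 2) 1L else 0L
    h1b <- if (b >= 1) 1L else 0L; h2b <- if (b == 2) 1L else 0L
    # assign the minor alleles to the first haplotype where possible
    hap_idx <- function(x, y) 4L - 2L * x - y  # (1,1)->1 (1,0)->2 (0,1)->3 (0,0)->4
    base[hap_idx(h1a, h1b)] <- base[hap_idx(h1a, h1b)] + 1
    base[hap_idx(h2a, h2b)] <- base[hap_idx(h2a, h2b)] + 1
  }

  f <- rep(0.25, 4)
  iter <- 0
  repeat {
    iter <- iter + 1
    # E step: split double heterozygotes between AB/ab and Ab/aB
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (denom > 0) f[1] * f[4] / denom else 0.5
    cnt <- base
    cnt[c(1, 4)] <- cnt[c(1, 4)] + ndh * w
    cnt[c(2, 3)] <- cnt[c(2, 3)] + ndh * (1 - w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }
  # observed-data log-likelihood (multinomial over genotype classes)
  loglik <- ld_obs_loglik(g1, g2, f)
  names(f) <- c("p11", "p10", "p01", "p00")
  list(freq = f, n = n, iterations = iter, loglik = loglik)
}

# Observed-data log-likelihood of unphased genotype pairs given haplotype
# frequencies (double heterozygote sums both phase resolutions).
ld_obs_loglik <- function(g1, g2, f) {
  prob_pair <- function(a, b) {
    if (a == 1 && b == 1) return(2 * f[1] * f[4] + 2 * f[2] * f[3])
    h1a <- if (a >= 1) 1L else 0L; h2a <- if (a == 2) 1L else 0L
    h1b <- if (b >= 1) 1L else 0L; h2b <- if (b == 2) 1L else 0L
    idx <- function(x, y) 4L - 2L * x - y
    i <- idx(h1a, h1b); j <- idx(h2a, h2b)
    if (i == j) f[i]^2 else 2 * f[i] * f[j]
  }
  sum(log(pmax(mapply(prob_pair, g1, g2), 1e-300)))
}

#' Two-locus linkage disequilibrium statistics
#'
#' From EM-estimated haplotype frequencies: D = p11 - pA pB; D' = D / Dmax
#' with the sign-appropriate frequency bound; the haplotype correlation r;
#' and a chi-square test chi2 = 2 N r^2 on 1 df.
#'
#' @param g1,g2 allele counts 0/1/2.
#' @return object of class `ld_result`: haplotype frequencies, D, Dprime, r,
#'   chi2, p, n.
#' @export
ld_stats <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (length(unique(g1[ok])) < 2 || length(unique(g2[ok])) < 2)
    stop("monomorphic locus: LD undefined", call. = FALSE)
  em <- estimate_haplotypes_em(g1, g2)
  f <- em$freq
  pA <- f[["p11"]] + f[["p10"]]
  pB <- f[["p11"]] + f[["p01"]]
  D <- f[["p11"]] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA))
          else min(pA * pB, (1 - pA) * (1 - pB))
  # Lewontin's D' is reported as a magnitude; the sign (coupling vs
  # repulsion) travels separately in `phase_sign` and in signed D.
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r <- if (denom > 0) D / sqrt(denom) else 0
  chi2 <- 2 * em$n * r^2
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(freq = f, D = D, Dprime = dprime, phase_sign = sign(D),
                 r = r, chi2 = chi2, p = p, n = em$n),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("Two-locus LD (n = %d): D = %.4f, D' = %.4f, r = %.4f, chi2 = %.2f, p = %.3g\n",
              x$n, x$D, x$Dprime, x$r, x$chi2, x$p))
  cat("Haplotype frequencies:",
      paste(sprintf("%s = %.4f", names(x$freq), x$freq), collapse = ", "), "\n")
  invisible(x)
}
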