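# Shared small fixtures, all generated in code.

small_cohort <- function(seed = 1, sizes = c("HC-CN" = 36, "PD-CN" = 14,
                                             "PD-MCI" = 19, "PD-D" = 32,
                                             "AD-D" = 35)) {
  generate_subjects(cohort_config(group_sizes = sizes, seed = seed))
}

# cohort + assay + processed matrix in one call
small_processed <- function(seed = 1, effects = list(), ...) {
  s <- small_cohort(seed)
  a <- generate_raw_assay(s, effects, seed = seed + 1000, ...)
  list(subjects = s, assay = a, pm = preprocess_assay(a, s))
}

# independent step-up BH oracle (straight from the definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# direct haplotype counting when no double heterozygotes are present
hap_count_oracle <- function(g1, g2) {
  cnt <- c(p11 = 0, p10 = 0, p01 = 0, p00 = 0)
  for (i in seq_along(g1)) {
    a <- g1[i]; b <- g2[i]
    h1 <- c(as.integer(a >= 1), as.integer(b >= 1))
    h2 <- c(as.integer(a == 2), as.integer(b == 2))
    key <- function(h) c("00" = "p00", "01" = "p01", "10" = "p10",
                         "11" = "p11")[paste0(h[1], h[2])]
    cnt[key(h1)] <- cnt[key(h1)] + 1
    cnt[key(h2)] <- cnt[key(h2)] + 1
  }
  cnt / (2 * length(g1))
}
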