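test_that("generate_subjects honours group sizes, empty groups and seed determinism", {
  s <- small_cohort(seed = 3)
  expect_equal(nrow(s), 136)
  expect_equal(as.vector(table(s$group)[c("HC-CN", "PD-CN", "PD-MCI",
                                          "PD-D", "AD-D")]),
               c(36, 14, 19, 32, 35))
  s0 <- small_cohort(seed = 3, sizes = c("HC-CN" = 0, "AD-D" = 10))
  expect_false("HC-CN" %in% s0$group)
  expect_equal(nrow(s0), 10)
  expect_identical(small_cohort(seed = 9), small_cohort(seed = 9))
  expect_false(identical(small_cohort(seed = 9), small_cohort(seed = 10)))
  # controls never levodopa-exposed, PD exposure fraction respects config
  expect_true(all(s$levodopa_exposed[s$group %in% c("HC-CN", "AD-D")] == 0))
})

test_that("cohort_config validates inputs", {
  expect_error(cohort_config(group_sizes = c(-1)), "named")
  expect_error(cohort_config(group_sizes = c(A = -1)), ">= 0")
  expect_error(cohort_config(levodopa_fraction = 1.5), "levodopa_fraction")
})

test_that("raw assay plants effects, carries well types, flags errors", {
  s <- small_cohort(seed = 2)
  expect_error(generate_raw_assay(s, list(effect_spec("nope", "AD-D", 1))),
               "unknown metabolite")
  expect_error(generate_raw_assay(s, list(effect_spec("Hcy", "XX", 1))),
               "absent from cohort")
  a <- generate_raw_assay(s, list(effect_spec("biotin", "AD-D", -0.73)),
                          seed = 5)
  expect_setequal(unique(a$wells$well_type),
                  c("sample", "blank", "qc", "calibrator"))
  # each plate has the advertised blanks and calibrators per metabolite
  w <- a$wells
  for (pl in 1:2) {
    expect_gte(sum(w$well_type == "blank" & w$plate == pl &
                     w$metabolite == "Hcy"), 3)
    expect_gte(sum(w$well_type == "calibrator" & w$plate == pl &
                     w$metabolite == "Hcy"), 7)
  }
  # determinism
  a2 <- generate_raw_assay(s, list(effect_spec("biotin", "AD-D", -0.73)),
                           seed = 5)
  expect_identical(a$wells, a2$wells)
})

test_that("null assay leaves group means within sampling error of each other", {
  s <- small_cohort(seed = 11)
  a <- generate_raw_assay(s, list(), plate_offset_sd = 0, seed = 12)
  w <- a$wells[a$wells$well_type == "sample" & a$wells$metabolite == "PLP", ]
  lc <- log(w$signal)
  means <- tapply(lc, s$group[match(w$subject_id, s$subject_id)], mean)
  # panel log SD for PLP is 0.45; group SE ~ 0.45/sqrt(14..36)
  expect_lt(max(means) - min(means), 4 * 0.45 / sqrt(14))
})

test_that("levodopa-exposed PD subjects show elevated DOPA", {
  s <- small_cohort(seed = 21)
  a <- generate_raw_assay(s, list(), seed = 22)
  w <- a$wells[a$wells$well_type == "sample" & a$wells$metabolite == "DOPA", ]
  lc <- log(w$signal - 2)  # subtract response intercept before inspecting
  exp_flag <- s$levodopa_exposed[match(w$subject_id, s$subject_id)]
  expect_gt(mean(lc[exp_flag == 1]), mean(lc[exp_flag == 0]) + 1)
})

test_that("genotypes follow HWE at the stated MAF", {
  s <- data.frame(subject_id = sprintf("S%05d", 1:10000),
                  group = "HC-CN", stringsAsFactors = FALSE)
  G <- generate_genotypes(s, list(snp_spec("a", 0.3)), seed = 7)
  hm <- mean(G[, "a"] == 2)
  se <- sqrt(0.09 * 0.91 / 10000)
  expect_lt(abs(hm - 0.09), 3 * se)
})

test_that("HWE goodness of fit holds across seeds", {
  s <- data.frame(subject_id = sprintf("S%05d", 1:10000),
                  group = "HC-CN", stringsAsFactors = FALSE)
  pass <- vapply(1:100, function(sd) {
    G <- generate_genotypes(s, list(snp_spec("a", 0.2)), seed = sd)
    obs <- tabulate(G[, "a"] + 1L, 3L)
    expct <- c(0.8^2, 2 * 0.2 * 0.8, 0.2^2) * 10000
    stats::chisq.test(obs, p = expct / 10000)$p.value > 0.001
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("repulsion-phase LD pair has no double-mutant haplotype", {
  s <- data.frame(subject_id = sprintf("S%05d", 1:5000),
                  group = "HC-CN", stringsAsFactors = FALSE)
  specs <- list(snp_spec("x", 0.3), snp_spec("y", 0.25))
  G <- generate_genotypes(s, specs,
                          list(ld_spec(c("x", "y"), 1, "repulsion")),
                          seed = 4)
  # at D' = 1 in repulsion no subject can be Hm at one locus and carry the
  # other minor allele on the same haplotype: no Hm-Hm and no Het-Hm pairs
  expect_equal(sum(G[, "x"] == 2 & G[, "y"] >= 1), 0)
  expect_equal(sum(G[, "y"] == 2 & G[, "x"] >= 1), 0)
})

test_that("independent LD pair estimates near-zero D-prime at n=10,000", {
  s <- data.frame(subject_id = sprintf("S%05d", 1:10000),
                  group = "HC-CN", stringsAsFactors = FALSE)
  dps <- vapply(1:10, function(sd) {
    G <- generate_genotypes(s, list(snp_spec("x", 0.3), snp_spec("y", 0.3)),
                            seed = 100 + sd)
    ld_stats(G[, "x"], G[, "y"])$Dprime
  }, numeric(1))
  expect_lt(stats::median(dps), 0.05)
})

test_that("haplotype pool reproduces the requested MAFs and D-prime", {
  for (ph in c("coupling", "repulsion")) {
    h <- haplotype_pool(0.3, 0.2, 0.7, ph)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_equal(unname(h["p11"] + h["p10"]), 0.3, tolerance = 1e-12)
    expect_equal(unname(h["p11"] + h["p01"]), 0.2, tolerance = 1e-12)
    D <- unname(h["p11"]) - 0.3 * 0.2
    dmax <- if (D >= 0) min(0.3 * 0.8, 0.2 * 0.7) else min(0.06, 0.56)
    expect_equal(abs(D) / dmax, 0.7, tolerance = 1e-12)
  }
  expect_error(generate_genotypes(
    data.frame(subject_id = "S1", group = "A"),
    list(snp_spec("x", 0.3)), list(ld_spec(c("x", "y"), 1, "coupling"))),
    "undeclared")
})

test_that("group_odds enriches the allele frequency per group", {
  s <- data.frame(subject_id = sprintf("S%05d", 1:6000),
                  group = rep(c("A", "B"), each = 3000),
                  stringsAsFactors = FALSE)
  G <- generate_genotypes(
    s, list(snp_spec("x", 0.2, group_odds = c(B = 3))), seed = 6)
  fA <- mean(G[s$group == "A", "x"]) / 2
  fB <- mean(G[s$group == "B", "x"]) / 2
  expect_gt(fB, fA + 0.1)
})

test_that("planted classification rules behave at both noise extremes", {
  d <- data.frame(snpA = c(0, 0, 1, 2, 0), snpB = c(0, 1, 0, 0, 0))
  lab <- plant_classification_rule(d, ~ snpA == 0 & snpB == 0)
  expect_equal(lab, c(1L, 0L, 0L, 0L, 1L))
  set.seed(1)
  d2 <- data.frame(z = rnorm(500))
  lab2 <- plant_classification_rule(d2, ~ z < -1)
  expect_equal(mean(lab2), mean(d2$z < -1))
  # noise 0.5 destroys the association with the rule
  lab3 <- plant_classification_rule(d2, ~ z < -1, noise_rate = 0.5, seed = 2)
  expect_lt(abs(cor(lab3, as.integer(d2$z < -1))), 0.15)
  expect_error(plant_classification_rule(d, ~ missing_col > 0))
})
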