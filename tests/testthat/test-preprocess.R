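test_that("calibration recovers exact quadratics and falls back below 3 points", {
  x <- c(0.5, 1, 2, 4, 8, 16, 32)
  y <- 1 + 2 * x + 0.1 * x^2
  cal <- fit_calibration(x, y)
  expect_equal(unname(cal$coefficients), c(1, 2, 0.1), tolerance = 1e-9)
  expect_equal(apply_calibration(cal, y), x, tolerance = 1e-9)
  expect_warning(cal2 <- fit_calibration(c(1, 2), c(1, 2)), "identity")
  expect_equal(apply_calibration(cal2, c(3, 7)), c(3, 7))
})

test_that("noisy calibration recovers coefficients within sampling error", {
  set.seed(42)
  x <- rep(c(0.5, 1, 2, 4, 8, 16, 32), 10)
  ok <- 0
  for (i in 1:20) {
    y <- 1 + 2 * x + 0.1 * x^2 + rnorm(length(x), 0, 0.01)
    fit <- lm(y ~ x + I(x^2))
    cal <- fit_calibration(x, y)
    se <- summary(fit)$coefficients[, 2]
    ok <- ok + all(abs(cal$coefficients - c(1, 2, 0.1)) < 3 * se)
  }
  expect_gte(ok, 18)
})

test_that("LOD formula matches mean + 3.09 sd and is linear in blank SD", {
  expect_equal(compute_lod(c(8, 10, 12)), 16.18)
  expect_equal(compute_lod(c(5, 5, 5)), 5)
  expect_error(compute_lod(7), ">= 2")
  set.seed(1)
  b <- rnorm(10000, 100, 10)
  expect_lt(abs(compute_lod(b) - 130.9), 1)
  # doubling the spread doubles (LOD - mean)
  b2 <- 100 + 2 * (b - 100)
  expect_equal(compute_lod(b2) - mean(b2), 2 * (compute_lod(b) - mean(b)),
               tolerance = 1e-9)
})

test_that("below-LOD exclusion uses a strict majority", {
  lods <- matrix(10, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  sig <- cbind(a = c(rep(5, 6), rep(20, 4)),   # 60% below -> excluded
               b = c(rep(5, 5), rep(20, 5)),   # exactly 50% -> retained
               c = rep(20, 10))                # none below -> retained
  fl <- flag_below_lod(sig, lods, rep(1, 10))
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))
})

test_that("plate normalization removes offsets and preserves group effects", {
  set.seed(3)
  n <- 120
  group <- rep(c("HC", "PD"), n / 2)          # balanced within plates
  plate <- rep(c(1, 2), each = n / 2)
  base <- rnorm(n) + (group == "PD") * 1.0
  x <- base + (plate == 2) * 1.0
  xn <- normalize_across_plates(x, plate, group)
  # residual plate means (after removing group means) agree across plates
  r <- xn - ave(xn, group)
  expect_lt(abs(mean(r[plate == 1]) - mean(r[plate == 2])), 1e-9)
  # group difference preserved
  d0 <- mean(base[group == "PD"]) - mean(base[group == "HC"])
  d1 <- mean(xn[group == "PD"]) - mean(xn[group == "HC"])
  expect_lt(abs(d1 - d0), 0.15)
  # single plate is the identity
  expect_identical(normalize_across_plates(x, rep(1, n), group), x)
})

test_that("plate normalization preserves planted group effects over replicates", {
  set.seed(14)
  errs <- replicate(50, {
    n <- 136
    group <- sample(rep(c("HC", "A", "B"), length.out = n))
    plate <- sample(rep(1:2, length.out = n))
    x <- rnorm(n) + (group == "A") * 1.0 + c(-0.5, 0.7)[plate]
    xn <- normalize_across_plates(x, plate, group)
    (mean(xn[group == "A"]) - mean(xn[group == "HC"])) - 1.0
  })
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("Box-Cox lambda estimation brackets the truth", {
  set.seed(8)
  lam_ln <- replicate(100, estimate_boxcox_lambda(rlnorm(500)))
  expect_gte(mean(lam_ln > -0.15 & lam_ln < 0.15), 0.95)
  lam_g <- replicate(30, estimate_boxcox_lambda(rnorm(500, 20, 1)))
  expect_lt(abs(mean(lam_g) - 1), 0.6)   # identity-ish for Gaussian data
  expect_equal(apply_boxcox(c(1, 2, 5), 1), c(0, 1, 4))
  expect_equal(apply_boxcox(c(1, exp(1)), 0), c(0, 1))
  expect_error(apply_boxcox(c(-1, 2), 0.5), "positive")
})

test_that("Box-Cox estimate agrees with the MASS profile-likelihood oracle", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- rlnorm(300)^0.7
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lam_oracle <- bc$x[which.max(bc$y)]
  expect_lt(abs(estimate_boxcox_lambda(x) - lam_oracle), 0.02)
})

test_that("Tukey winsorization clamps to fences, keeps ranks, is idempotent", {
  x <- c(1:9, 100)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  hi <- q[2] + 3 * (q[2] - q[1])
  tw <- tukey_winsorize(x, k = 3)
  expect_equal(tw$values, c(1:9, hi))
  expect_equal(tw$n_adjusted, 1)
  expect_equal(rank(tw$values), rank(x))
  expect_equal(tukey_winsorize(tw$values, k = 3)$values, tw$values)
  clean <- c(2, 4, 6, 8)
  expect_equal(tukey_winsorize(clean)$values, clean)
})

test_that("standardization to controls gives control mean 0 / SD 1", {
  st <- standardize_to_controls(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(st$z, c(-1, 0, 1, 2))
  expect_error(standardize_to_controls(c(2, 2, 2, 5), c(TRUE, TRUE, TRUE, FALSE)),
               "zero control SD")
  set.seed(2)
  x <- rnorm(100); ctrl <- rep(c(TRUE, FALSE), 50)
  z <- standardize_to_controls(x, ctrl)$z
  expect_lt(abs(mean(z[ctrl])), 1e-12)
  expect_equal(stats::sd(z[ctrl]), 1, tolerance = 1e-12)
})

test_that("conditional-mean imputation fills cells and falls back when empty", {
  t0 <- data.frame(group = c("A", "A", "A", "B", "B"),
                   sex = c("F", "F", "F", "M", "M"),
                   bmi = c(25, 27, NA, 30, NA))
  t1 <- impute_conditional_mean(t0, "bmi")
  expect_equal(t1$bmi[3], 26)
  expect_equal(t1$bmi[5], 30)
  expect_identical(impute_conditional_mean(t1, "bmi"), t1)
  # empty (group, sex) cell -> group mean fallback
  t2 <- data.frame(group = c("A", "A", "B"), sex = c("F", "M", "F"),
                   bmi = c(25, NA, 30))
  t2$bmi[2] <- NA
  t3 <- suppressWarnings(impute_conditional_mean(
    data.frame(group = c("A", "B", "A"), sex = c("F", "F", "M"),
               bmi = c(25, 30, NA)), "bmi"))
  expect_equal(t3$bmi[3], 25)
})

test_that("half-minimum interpolation follows the non-detect convention", {
  expect_equal(half_min_interpolate(c(0.8, NA, 1.2, NA, NA, NA)),
               c(0.8, 0.4, 1.2, 0.4, 0.4, 0.4))
  expect_equal(half_min_interpolate(c(2.0, NA)), c(2.0, 1.0))
  expect_identical(half_min_interpolate(c(1, 2)), c(1, 2))
  expect_error(half_min_interpolate(c(NA_real_, NA_real_)), "no detected")
})

test_that("rare-SNP filter counts carriers with the documented boundary", {
  G <- cbind(four = c(rep(1, 4), rep(0, 16)),
             five = c(rep(1, 5), rep(0, 15)),
             mono = rep(0, 20),
             hm = c(rep(2, 3), rep(0, 17)))
  Gf <- filter_rare_snps(G, min_carriers = 5)
  expect_equal(colnames(Gf), "five")
  # allele mode counts alleles: 3 homozygotes = 6 alleles pass
  Ga <- filter_rare_snps(G, min_carriers = 5, mode = "alleles")
  expect_setequal(colnames(Ga), c("five", "hm"))
})

test_that("DOPA indicators flag only PD subjects above the control 95th percentile", {
  group <- c(rep("HC-CN", 51), "PD-D", "PD-CN")
  set.seed(1)
  ctrl <- c(rnorm(50), 3.0)   # one control with a very high value
  thr <- mean(ctrl) + 1.6449 * sd(ctrl)
  ld <- c(ctrl, thr + 0.05, thr - 0.10)
  di <- derive_dopa_indicators(ld, group)
  expect_equal(di$dopa_pdd[52], 1L)     # PD-D just above the threshold
  expect_equal(di$dopa_pdnd[53], 0L)    # PD-ND just below
  # controls are never flagged, however extreme their DOPA
  expect_equal(sum(di$dopa_pdd[1:51]) + sum(di$dopa_pdnd[1:51]), 0L)
  expect_lt(abs(attr(di, "threshold") - thr), 1e-12)
  expect_error(derive_dopa_indicators(ld, rep("PD-D", 53)), "controls")
})

test_that("full preprocessing yields control mean 0 / SD 1 per metabolite", {
  fx <- small_processed(seed = 31)
  z <- fx$pm$z
  ctrl <- fx$subjects$group == "HC-CN"
  for (m in colnames(z)) {
    expect_lt(abs(mean(z[ctrl, m])), 1e-10)
    expect_equal(stats::sd(z[ctrl, m]), 1, tolerance = 1e-10)
  }
  expect_true(all(c("lambda", "control_mean", "control_sd", "lod",
                    "excluded") %in% names(fx$pm$meta$Hcy)))
})
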