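toy_features <- function(n = 60, n_snps = 4, n_mets = 2, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * n_snps, 2, 0.3), n, n_snps,
              dimnames = list(NULL, paste0("s", seq_len(n_snps))))
  Z <- if (n_mets > 0)
    matrix(rnorm(n * n_mets), n, n_mets,
           dimnames = list(NULL, paste0("m", seq_len(n_mets))))
  list(G = G, Z = Z, features = gp_features(Z, G))
}

test_that("operand pool enumerates metabolite and SNP thresholds exactly", {
  tf <- toy_features(n = 30, n_snps = 20, n_mets = 10)
  ops <- tf$features$operands
  expect_equal(nrow(ops), 10 * 5 + 20 * 3 + 20)  # 130
  expect_setequal(unique(ops$threshold[ops$kind == "metabolite_threshold"]),
                  c(-2, -1, 0, 1, 2))
  expect_setequal(unique(ops$threshold[ops$kind == "snp_threshold"]),
                  c(0, 1, 2))
  met_only <- gp_features(tf$Z, NULL)
  expect_true(all(met_only$operands$kind == "metabolite_threshold"))
  expect_error(gp_features(NULL, NULL), "empty")
})

test_that("tree evaluation follows the comparator and coercion rules", {
  G <- rbind(c(snpA = 0, snpB = 0), c(snpA = 1, snpB = 0),
             c(snpA = 2, snpB = 2))
  ft <- gp_features(NULL, G)
  lab_idx <- function(l) which(ft$operands$label == l)
  # NOT(snpA>=1) AND NOT(snpB>=1): positive for the wild-type subject
  tree <- list(3L, list(1L, list(0L, lab_idx("snpA>=1"))),
               list(1L, list(0L, lab_idx("snpB>=1"))))
  expect_equal(eval_tree(tree, ft$matrix), c(1, 0, 0))
  # numeric product coerces to Boolean via > 0: counts (2,2) -> 4 -> TRUE
  tree2 <- list(6L, list(0L, lab_idx("count(snpA)")),
                list(0L, lab_idx("count(snpB)")))
  expect_equal(eval_tree(tree2, ft$matrix) > 0, c(FALSE, FALSE, TRUE))
  # constant-true tree classifies everyone positive: accuracies (1, 0)
  always <- list(0L, lab_idx("snpA>=0"))
  fit <- gp_fitness(always, ft, c(1, 0, 0))
  expect_equal(fit$acc_pos, 1)
  expect_equal(fit$acc_neg, 0)
})

test_that("fitness is the penalized mean of per-class accuracies", {
  # craft a 2-operand tree with per-class accuracies 0.91 and 0.70
  n_pos <- 100; n_neg <- 100
  pred <- c(rep(1, 91), rep(0, 9), rep(1, 30), rep(0, 70))
  G <- cbind(snpA = ifelse(pred == 1, 1, 0), snpB = ifelse(pred == 1, 1, 0))
  ft <- gp_features(NULL, G)
  labels <- rep(c(1, 0), c(n_pos, n_neg))
  li <- function(l) which(ft$operands$label == l)
  tree <- list(3L, list(0L, li("snpA>=1")), list(0L, li("snpB>=1")))
  fit <- gp_fitness(tree, ft, labels)
  expect_equal(fit$acc_pos, 0.91)
  expect_equal(fit$acc_neg, 0.70)
  expect_equal(fit$n_operands, 2)
  expect_equal(fit$fitness, 0.805 - 0.10)
  # a perfect 1-operand tree scores 0.95
  lab2 <- as.integer(G[, "snpA"] >= 1)
  fit2 <- gp_fitness(list(0L, li("snpA>=1")), ft, lab2)
  expect_equal(fit2$fitness, 0.95)
})

test_that("adding a redundant operand lowers fitness by exactly the penalty", {
  tf <- toy_features(seed = 3)
  ft <- tf$features
  labels <- as.integer(tf$G[, "s1"] >= 1)
  li <- which(ft$operands$label == "s1>=1")
  t1 <- list(0L, li)
  t2 <- list(2L, list(0L, li), list(0L, li))  # OR(x, x): same predictions
  f1 <- gp_fitness(t1, ft, labels)
  f2 <- gp_fitness(t2, ft, labels)
  expect_equal(f1$fitness - f2$fitness, 0.05, tolerance = 1e-12)
})

test_that("evolution recovers a planted Boolean rule and is deterministic", {
  tf <- toy_features(n = 80, n_snps = 6, n_mets = 0, seed = 4)
  labels <- plant_classification_rule(as.data.frame(tf$G), ~ s1 == 0 & s2 == 0)
  ft <- gp_features(NULL, tf$G)
  cfg <- gp_config(population = 1500, generations = 15, runs = 2, seed = 9)
  r1 <- gp_evolve(ft, labels, cfg)
  expect_gte(r1$acc_pos, 0.95)
  expect_gte(r1$acc_neg, 0.95)
  r2 <- gp_evolve(ft, labels, cfg)
  expect_identical(r1$tree, r2$tree)
  expect_identical(r1$fitness, r2$fitness)
  # prediction on the training features reproduces the fitted accuracies
  pred <- predict(r1, ft)
  expect_equal(mean(pred[labels == 1] == 1), r1$acc_pos)
})

test_that("random labels cap the achievable noise-free fitness near chance", {
  set.seed(6)
  tf <- toy_features(n = 100, n_snps = 5, n_mets = 2, seed = 6)
  labels <- rbinom(100, 1, 0.5)
  cfg <- gp_config(population = 500, generations = 10, runs = 1, seed = 7)
  r <- gp_evolve(tf$features, labels, cfg)
  expect_lte(r$fitness, 0.72)  # some overfit headroom above 0.5 at n=100
})

test_that("degenerate evolution bounds: population 2, zero generations", {
  tf <- toy_features(n = 40, seed = 8)
  labels <- as.integer(tf$G[, "s1"] >= 1)
  cfg <- gp_config(population = 2, generations = 0, runs = 1, seed = 3)
  r <- gp_evolve(tf$features, labels, cfg)
  expect_s3_class(r, "gp_result")
  expect_true(is.finite(r$fitness))
  expect_lte(tree_depth(r$tree), 6)
})

test_that("best-of-runs fitness is monotone in the number of runs", {
  tf <- toy_features(n = 60, seed = 10)
  labels <- as.integer(tf$G[, "s2"] >= 1)
  fits <- sapply(1:3, function(R) {
    cfg <- gp_config(population = 200, generations = 5, runs = R, seed = 5)
    gp_evolve(tf$features, labels, cfg)$fitness
  })
  expect_true(all(diff(fits) >= -1e-12))
})

test_that("trees respect the depth cap through mutation and crossover", {
  set.seed(11)
  for (i in 1:50) {
    t1 <- random_tree(10, 6); t2 <- random_tree(10, 6)
    expect_lte(tree_depth(crossover_trees(t1, t2, 6)), 6)
    expect_lte(tree_depth(mutate_tree(t1, 10, 6)), 6)
  }
})

test_that("cross-validation folds partition subjects and hit chance on noise", {
  set.seed(12)
  tf <- toy_features(n = 60, n_snps = 4, n_mets = 0, seed = 12)
  labels <- plant_classification_rule(as.data.frame(tf$G), ~ s1 == 0)
  cfg <- gp_config(population = 300, generations = 8, runs = 1, seed = 2)
  cv <- gp_cv(tf$features, labels, cfg, k = 5)
  expect_equal(nrow(cv$folds), 5)
  expect_gte(cv$acc_pos, 0.8)   # one-operand rule generalizes
  expect_error(gp_cv(tf$features, labels, cfg, k = 1), "k must be")
})
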