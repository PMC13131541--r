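#' Operand pool for the expression-tree classifier
#'
#' Enumerates the discrete operand set: for every metabolite a Boolean
#' threshold test (z >= t) at t in {-2, -1, 0, 1, 2} SD from the control
#' mean; for every SNP a Boolean threshold on the number of affected alleles
#' (g >= t, t in {0, 1, 2}) plus a numeric allele-count operand. Operand
#' values are materialized once into an n x K matrix so tree evaluation is a
#' sequence of vectorized column operations.
#'
#' @param z matrix subjects x metabolites of control-standardized values
#'   (may be NULL).
#' @param genotypes matrix subjects x SNPs of allele counts (may be NULL).
#' @return object of class `gp_features`: `operands` (data.frame kind,
#'   feature, threshold, label), `matrix` (n x K numeric), `n`.
#' @export
gp_features <- function(z = NULL, genotypes = NULL) {
  if (is.null(z) && is.null(genotypes)) stop("empty feature set", call. = FALSE)
  ops <- list(); cols <- list()
  if (!is.null(z)) {
    for (m in colnames(z)) for (t in c(-2, -1, 0, 1, 2)) {
      ops[[length(ops) + 1L]] <- data.frame(
        kind = "metabolite_threshold", feature = m, threshold = t,
        label = sprintf("%s>=%g", m, t), stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- as.numeric(z[, m] >= t)
    }
  }
  if (!is.null(genotypes)) {
    for (s in colnames(genotypes)) {
      for (t in c(0, 1, 2)) {
        ops[[length(ops) + 1L]] <- data.frame(
          kind = "snp_threshold", feature = s, threshold = t,
          label = sprintf("%s>=%d", s, t), stringsAsFactors = FALSE)
        cols[[length(cols) + 1L]] <- as.numeric(genotypes[, s] >= t)
      }
      ops[[length(ops) + 1L]] <- data.frame(
        kind = "snp_count", feature = s, threshold = NA_real_,
        label = sprintf("count(%s)", s), stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- as.numeric(genotypes[, s])
    }
  }
  operands <- do.call(rbind, ops)
  M <- do.call(cbind, cols)
  colnames(M) <- operands$label
  n <- nrow(M)
  structure(list(operands = operands, matrix = M, n = n),
            class = "gp_features")
}

#' @export
print.gp_features <- function(x, ...) {
  cat("GP operand pool:", nrow(x$operands), "operands x", x$n, "subjects\n")
  invisible(x)
}

# operator codes: 1 NOT, 2 OR, 3 AND, 4 ADD, 5 SUB, 6 MUL, 7 NEG; 0 leaf
gp_op_names <- c("NOT", "OR", "AND", "ADD", "SUB", "MUL", "NEG")
gp_unary <- c(1L, 7L)
gp_binary <- c(2L, 3L, 4L, 5L, 6L)

# Evaluate a tree into a numeric vector over all rows of the operand matrix.
# Booleans are 0/1; numeric values coerce to Boolean via "> 0".
eval_tree <- function(node, M) {
  op <- node[[1L]]
  if (op == 0L) return(M[, node[[2L]]])
  if (op == 1L) return(as.numeric(!(eval_tree(node[[2L]], M) > 0)))
  if (op == 7L) return(-eval_tree(node[[2L]], M))
  a <- eval_tree(node[[2L]], M); b <- eval_tree(node[[3L]], M)
  switch(op - 1L,
         as.numeric(a > 0 | b > 0),   # OR
         as.numeric(a > 0 & b > 0),   # AND
         a + b, a - b, a * b)
}

count_operands <- function(node) {
  op <- node[[1L]]
  if (op == 0L) return(1L)
  if (op == 1L || op == 7L) return(count_operands(node[[2L]]))
  count_operands(node[[2L]]) + count_operands(node[[3L]])
}

tree_depth <- function(node) {
  op <- node[[1L]]
  if (op == 0L) return(1L)
  if (op == 1L || op == 7L) return(1L + tree_depth(node[[2L]]))
  1L + max(tree_depth(node[[2L]]), tree_depth(node[[3L]]))
}

n_nodes <- function(node) {
  op <- node[[1L]]
  if (op == 0L) return(1L)
  if (op == 1L || op == 7L) return(1L + n_nodes(node[[2L]]))
  1L + n_nodes(node[[2L]]) + n_nodes(node[[3L]])
}

random_tree <- function(K, max_depth, p_leaf = 0.35) {
  if (max_depth <= 1L || stats::runif(1) < p_leaf)
    return(list(0L, as.integer(stats::runif(1) * K) + 1L))
  op <- as.integer(stats::runif(1) * 7) + 1L
  if (op == 1L || op == 7L)
    list(op, random_tree(K, max_depth - 1L, p_leaf))
  else
    list(op, random_tree(K, max_depth - 1L, p_leaf),
         random_tree(K, max_depth - 1L, p_leaf))
}

# k-th node of the tree in preorder (k = 1 is the root)
nth_subtree <- function(node, k) {
  if (k == 1L) return(node)
  k <- k - 1L
  sz <- n_nodes(node[[2L]])
  if (k <= sz) return(nth_subtree(node[[2L]], k))
  nth_subtree(node[[3L]], k - sz)
}

# replace the k-th preorder node by `sub`; depth-limited generators get the
# remaining room via `room_fn(depth_of_node)`
replace_nth <- function(node, k, sub) {
  if (k == 1L) return(sub)
  k <- k - 1L
  sz <- n_nodes(node[[2L]])
  if (k <= sz) {
    node[[2L]] <- replace_nth(node[[2L]], k, sub)
  } else {
    node[[3L]] <- replace_nth(node[[3L]], k - sz, sub)
  }
  node
}

# depth (1-based) of the k-th preorder node
nth_depth <- function(node, k) {
  if (k == 1L) return(1L)
  k <- k - 1L
  sz <- n_nodes(node[[2L]])
  if (k <= sz) return(1L + nth_depth(node[[2L]], k))
  1L + nth_depth(node[[3L]], k - sz)
}

mutate_tree <- function(tree, K, max_depth) {
  nn <- n_nodes(tree)
  k <- as.integer(stats::runif(1) * nn) + 1L
  room <- max_depth - nth_depth(tree, k) + 1L
  replace_nth(tree, k, random_tree(K, max(1L, room)))
}

crossover_trees <- function(t1, t2, max_depth) {
  n1 <- n_nodes(t1); n2 <- n_nodes(t2)
  for (attempt in 1:5) {
    a <- as.integer(stats::runif(1) * n1) + 1L
    b <- as.integer(stats::runif(1) * n2) + 1L
    sub <- nth_subtree(t2, b)
    if (nth_depth(t1, a) - 1L + tree_depth(sub) > max_depth) next
    return(replace_nth(t1, a, sub))
  }
  t1
}

#' Penalized fitness of an expression tree
#'
#' Mean of the two per-class accuracies minus 0.05 per operand; the noise
#' term (uniform on `[0, amp]`) is added only during evolution's selection —
#' reported fitness is always noise free.
#'
#' @param tree expression tree (internal representation, or from a
#'   `gp_result`).
#' @param features a [gp_features()] pool.
#' @param labels 0/1 class labels.
#' @param penalty per-operand penalty (default 0.05).
#' @return list: fitness (noise free), acc_pos, acc_neg, n_operands.
#' @export
gp_fitness <- function(tree, features, labels, penalty = 0.05) {
  M <- features$matrix
  ok <- stats::complete.cases(M) & !is.na(labels)
  pred <- eval_tree(tree, M)[ok] > 0
  lab <- labels[ok]
  if (!any(lab == 1) || !any(lab == 0))
    stop("both classes must be non-empty", call. = FALSE)
  acc_pos <- mean(pred[lab == 1])
  acc_neg <- mean(!pred[lab == 0])
  nop <- count_operands(tree)
  list(fitness = (acc_pos + acc_neg) / 2 - penalty * nop,
       acc_pos = acc_pos, acc_neg = acc_neg, n_operands = nop)
}

#' Configuration of the genetic-programming search
#'
#' Full-scale defaults follow the study design (population 100,000, 100
#' generations, best of 10 runs, 5-p.p. operand penalty, annealing noise up
#' to 10 p.p. decaying to zero over the first half of the run); the
#' `scaled_down = TRUE` preset (population 2,000, 20 generations, 3 runs)
#' keeps test workloads tractable while preserving the dynamics.
#'
#' @param population population size.
#' @param generations evolution steps.
#' @param runs independent restarts; the best noise-free fitness wins.
#' @param penalty per-operand fitness penalty.
#' @param noise_max initial selection-noise amplitude.
#' @param tournament_size selection tournament size.
#' @param p_crossover,p_mutation,p_fresh offspring operation mix (fresh =
#'   new random individual).
#' @param max_depth tree depth cap.
#' @param seed integer seed.
#' @param scaled_down use the reduced preset.
#' @return list of class `gp_config`.
#' @export
gp_config <- function(population = if (scaled_down) 2000L else 100000L,
                      generations = if (scaled_down) 20L else 100L,
                      runs = if (scaled_down) 3L else 10L,
                      penalty = 0.05, noise_max = 0.10,
                      tournament_size = 4L,
                      p_crossover = 0.6, p_mutation = 0.3, p_fresh = 0.1,
                      max_depth = 6L, seed = 1L, scaled_down = TRUE) {
  stopifnot(population >= 2, penalty >= 0, penalty <= 1,
            noise_max >= 0, noise_max <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 runs = as.integer(runs), penalty = penalty,
                 noise_max = noise_max,
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 p_fresh = p_fresh, max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "gp_config")
}

#' Evolve an expression-tree classifier
#'
#' Runs `runs` independent evolutions. Each initializes a random population
#' and iterates tournament selection with crossover, mutation and fresh
#' recombination; a uniform noise term on `[0, amp]` perturbs fitness during
#' selection, with amp decreasing linearly from `noise_max` to 0 over the
#' first half of the generations (simulated-annealing style) and 0 after.
#' The best individual by noise-free fitness across all runs is returned.
#'
#' @param features a [gp_features()] pool.
#' @param labels 0/1 labels (both classes non-empty).
#' @param config a [gp_config()].
#' @return object of class `gp_result`: `tree`, `expression` (serialized),
#'   `fitness`, `acc_pos`, `acc_neg`, `n_operands`, `operands`, `config`.
#' @export
gp_evolve <- function(features, labels, config = gp_config()) {
  M <- features$matrix
  ok <- stats::complete.cases(M) & !is.na(labels)
  M <- M[ok, , drop = FALSE]
  lab <- labels[ok]
  if (!any(lab == 1) || !any(lab == 0))
    stop("both classes must be non-empty", call. = FALSE)
  K <- ncol(M)
  pos <- lab == 1; neg <- lab == 0
  npos <- sum(pos); nneg <- sum(neg)
  pen <- config$penalty

  fit_of <- function(tree) {
    v <- eval_tree(tree, M) > 0
    (sum(v[pos]) / npos + sum(!v[neg]) / nneg) / 2 -
      pen * count_operands(tree)
  }

  rng <- local_rng(config$seed)
  on.exit(rng())
  best <- NULL
  half <- config$generations / 2
  for (run in seq_len(config$runs)) {
    trees <- lapply(seq_len(config$population), function(i)
      random_tree(K, config$max_depth))
    fits <- vapply(trees, fit_of, numeric(1))
    npop <- config$population
    ts <- config$tournament_size
    if (config$generations > 0) for (gen in seq_len(config$generations)) {
      amp <- if (half > 0) config$noise_max * max(0, 1 - (gen - 1) / half) else 0
      noisy <- fits + if (amp > 0) stats::runif(length(fits), 0, amp) else 0
      elite <- which.max(fits)
      u <- stats::runif(npop - 1L)
      n_parents <- sum(u < config$p_crossover) * 2L +
        sum(u >= config$p_crossover & u < config$p_crossover + config$p_mutation)
      # batched tournaments: each row is one tournament, winner by noisy fitness
      winners <- integer(0)
      if (n_parents > 0) {
        cand <- matrix(sample.int(npop, n_parents * ts, replace = TRUE),
                       n_parents, ts)
        wcol <- max.col(matrix(noisy[cand], n_parents, ts),
                        ties.method = "first")
        winners <- cand[cbind(seq_len(n_parents), wcol)]
      }
      wi <- 0L
      new_trees <- vector("list", npop)
      new_trees[[1L]] <- trees[[elite]]
      for (i in 2:npop) {
        r <- u[i - 1L]
        new_trees[[i]] <- if (r < config$p_crossover) {
          wi <- wi + 2L
          crossover_trees(trees[[winners[wi - 1L]]], trees[[winners[wi]]],
                          config$max_depth)
        } else if (r < config$p_crossover + config$p_mutation) {
          wi <- wi + 1L
          mutate_tree(trees[[winners[wi]]], K, config$max_depth)
        } else {
          random_tree(K, config$max_depth)
        }
      }
      new_fits <- vapply(new_trees, fit_of, numeric(1))
      new_fits[1L] <- fits[elite]
      trees <- new_trees; fits <- new_fits
    }
    i <- which.max(fits)
    if (is.null(best) || fits[i] > best$fitness)
      best <- list(tree = trees[[i]], fitness = fits[i])
  }
  detail <- gp_fitness(best$tree, features, labels, pen)
  structure(list(tree = best$tree,
                 expression = serialize_tree(best$tree, features$operands),
                 fitness = detail$fitness,
                 acc_pos = detail$acc_pos, acc_neg = detail$acc_neg,
                 n_operands = detail$n_operands,
                 operands = features$operands, config = config),
            class = "gp_result")
}

#' @export
print.gp_result <- function(x, ...) {
  cat("GP expression-tree classifier\n")
  cat("  ", x$expression, "\n", sep = "")
  cat(sprintf("  fitness %.4f (acc+ %.1f%%, acc- %.1f%%, %d operands, penalty %.2f/operand)\n",
              x$fitness, 100 * x$acc_pos, 100 * x$acc_neg, x$n_operands,
              x$config$penalty))
  invisible(x)
}

#' @export
predict.gp_result <- function(object, features, ...) {
  stopifnot(inherits(features, "gp_features"))
  if (!identical(features$operands$label, object$operands$label))
    stop("operand pool mismatch; rebuild gp_features with the same columns",
         call. = FALSE)
  as.integer(eval_tree(object$tree, features$matrix) > 0)
}

serialize_tree <- function(node, operands) {
  op <- node[[1L]]
  if (op == 0L) return(operands$label[node[[2L]]])
  if (op %in% gp_unary)
    return(sprintf("%s(%s)", gp_op_names[op],
                   serialize_tree(node[[2L]], operands)))
  sprintf("%s(%s, %s)", gp_op_names[op],
          serialize_tree(node[[2L]], operands),
          serialize_tree(node[[3L]], operands))
}

#' Stratified k-fold cross-validation of the GP classifier
#'
#' Folds are stratified by class; per fold the classifier is evolved on the
#' training portion and evaluated on the held-out subjects; mean per-class
#' accuracies are reported.
#'
#' @param features a [gp_features()] pool.
#' @param labels 0/1 labels.
#' @param config a [gp_config()].
#' @param k number of folds.
#' @return list: `acc_pos`, `acc_neg` (means over folds), `folds`
#'   (data.frame per fold).
#' @export
gp_cv <- function(features, labels, config = gp_config(), k = 10) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  rng <- local_rng(config$seed)
  on.exit(rng())
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(labels[te] == 1) && !any(labels[te] == 0)) next
    sub_cfg <- config; sub_cfg$seed <- config$seed + f
    ftr <- features; ftr$matrix <- features$matrix[tr, , drop = FALSE]
    ftr$n <- sum(tr)
    fit <- gp_evolve(ftr, labels[tr], sub_cfg)
    fte <- features; fte$matrix <- features$matrix[te, , drop = FALSE]
    fte$n <- sum(te)
    pred <- predict(fit, fte)
    lab <- labels[te]
    rows[[f]] <- data.frame(
      fold = f,
      acc_pos = if (any(lab == 1)) mean(pred[lab == 1] == 1) else NA_real_,
      acc_neg = if (any(lab == 0)) mean(pred[lab == 0] == 0) else NA_real_)
  }
  folds <- do.call(rbind, rows)
  list(acc_pos = mean(folds$acc_pos, na.rm = TRUE),
       acc_neg = mean(folds$acc_neg, na.rm = TRUE), folds = folds)
}
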