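#' Linear regression with group-specific residual variance
#'
#' Fits y = X b + e with SD(e_i) = sigma * m_{g(i)} where g(i) is a
#' grouping factor (typically the subject group) and the multiplier of the
#' reference (first) level is fixed at 1 (`multipliers` are relative
#' residual SDs, the varIdent convention). Estimation is by full maximum
#' likelihood via iterated generalized least squares: coefficients by
#' weighted least squares given the multipliers, multipliers by the
#' group-wise mean squared residuals, iterated until the log-likelihood is
#' stable. With a single variance group the fit coincides with ordinary
#' least squares.
#'
#' Wald t statistics use the GLS covariance (X' W X)^-1 with residual
#' degrees of freedom n - p.
#'
#' @param formula model formula.
#' @param data data.frame with model variables.
#' @param variance_group name of the factor in `data` (or a vector) defining
#'   the variance groups; NULL for homoscedastic OLS.
#' @param reltol relative log-likelihood convergence tolerance.
#' @param max_iter maximum IGLS iterations.
#' @return object of class `hetlm`.
#' @examples
#' d <- data.frame(y = rnorm(60), x = rnorm(60),
#'                 g = rep(c("a", "b"), each = 30))
#' fit <- hetlm(y ~ x, d, variance_group = "g")
#' coef(fit); summary(fit)
#' @export
hetlm <- function(formula, data, variance_group = NULL,
                  reltol = 1e-8, max_iter = 200) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  omitted <- attr(mf, "na.action")
  keep <- if (is.null(omitted)) seq_len(nrow(data))
          else setdiff(seq_len(nrow(data)), as.integer(omitted))
  if (is.null(variance_group)) {
    g <- factor(rep("all", n))
  } else if (is.character(variance_group) && length(variance_group) == 1) {
    g <- droplevels(factor(data[[variance_group]][keep]))
  } else {
    g <- droplevels(factor(variance_group[keep]))
  }
  levs <- levels(g)
  k <- length(levs)
  if (n <= p + k) stop("too few observations for the requested model",
                       call. = FALSE)
  gi <- as.integer(g)
  ng <- tabulate(gi, k)

  loglik_fn <- function(res, s2g) {
    -n / 2 * log(2 * pi) - sum(ng * log(s2g)) / 2 -
      sum(res^2 / s2g[gi]) / 2
  }

  # IGLS: start at OLS
  w <- rep(1, n)
  beta <- qr.coef(qrX, y)
  res <- y - as.vector(X %*% beta)
  s2g <- vapply(seq_len(k), function(j) mean(res[gi == j]^2), numeric(1))
  ll <- loglik_fn(res, s2g)
  converged <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- 1 / s2g[gi]
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y * sw)
    beta <- fit$coefficients
    res <- y - as.vector(X %*% beta)
    s2g_new <- vapply(seq_len(k), function(j) mean(res[gi == j]^2), numeric(1))
    ll_new <- loglik_fn(res, s2g_new)
    if (is.finite(ll) && abs(ll_new - ll) < reltol * (abs(ll) + reltol)) {
      converged <- TRUE
      s2g <- s2g_new; ll <- ll_new
      break
    }
    s2g <- s2g_new; ll <- ll_new
  }

  w <- 1 / s2g[gi]
  # Wald covariance uses the unbiased residual-variance scale n/(n - p):
  # with one variance group this reproduces OLS standard errors exactly,
  # and it removes the small-sample anti-conservatism of pure-ML SEs.
  XtWX <- crossprod(X * sqrt(w)) * (n - p) / n
  vcov <- solve(XtWX)
  se <- sqrt(diag(vcov))
  tval <- beta / se
  df <- n - p
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  # relative residual SDs, reference level fixed at 1 (varIdent convention)
  multipliers <- sqrt(s2g / s2g[1L])
  names(multipliers) <- levs
  names(s2g) <- levs

  structure(list(
    coefficients = beta, se = se, tvals = tval, pvals = pval,
    vcov = vcov, df.residual = df, sigma2 = s2g,
    multipliers = multipliers, logLik = ll,
    converged = converged, iterations = iter,
    fitted.values = as.vector(X %*% beta), residuals = res,
    weights = w, groups = g, n = n, rank = p,
    call = match.call(), terms = attr(mf, "terms"), model = mf,
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf)
  ), class = "hetlm")
}

#' @export
print.hetlm <- function(x, ...) {
  cat("Group-heteroscedastic linear model (ML)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, 4))
  cat("\nVariance multipliers (reference = 1):\n")
  print(round(x$multipliers, 4))
  if (!x$converged) cat("\nWARNING: IGLS did not converge in",
                        x$iterations, "iterations\n")
  invisible(x)
}

#' @export
summary.hetlm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tvals, `Pr(>|t|)` = object$pvals)
  out <- list(call = object$call, coefficients = tab,
              multipliers = object$multipliers, sigma2 = object$sigma2,
              df = object$df.residual, logLik = object$logLik,
              converged = object$converged)
  class(out) <- "summary.hetlm"
  out
}

#' @export
print.summary.hetlm <- function(x, ...) {
  cat("Group-heteroscedastic linear model (ML)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual df:", x$df, "  log-likelihood:", format(x$logLik), "\n")
  cat("Variance multipliers:\n")
  print(round(x$multipliers, 4))
  invisible(x)
}

#' @export
coef.hetlm <- function(object, ...) object$coefficients

#' @export
vcov.hetlm <- function(object, ...) object$vcov

#' @export
logLik.hetlm <- function(object, ...) {
  structure(object$logLik, df = object$rank + length(object$sigma2),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.hetlm <- function(object, ...) object$n

#' @export
predict.hetlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  as.vector(X %*% object$coefficients)
}

#' @export
residuals.hetlm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") r <- r * sqrt(object$weights)
  r
}

#' @export
fitted.hetlm <- function(object, ...) object$fitted.values

#' @export
simulate.hetlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdv <- sqrt(object$sigma2[as.integer(object$groups)])
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(object$n, 0, sdv)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Pairwise Pearson collinearity of a design matrix
#'
#' Maximum absolute off-diagonal Pearson correlation over numeric regressor
#' pairs; constant columns are excluded with a warning.
#'
#' @param design numeric matrix or data.frame of regressors (no intercept).
#' @return list with `max_abs_r` and the full correlation matrix.
#' @export
pearson_collinearity <- function(design) {
  X <- as.matrix(design)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0)) {
    warning("constant columns excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need >= 2 non-constant regressors", call. = FALSE)
  R <- stats::cor(X, use = "pairwise.complete.obs")
  diag(R) <- 0
  list(max_abs_r = max(abs(R)), cor = R)
}

#' Adjusted generalized variance-inflation factors
#'
#' GVIF per term group via the determinant-ratio formula on the regressor
#' correlation matrix: GVIF = det(R_11) det(R_22) / det(R), adjusted as
#' GVIF^(1/(2 df)) so values are comparable across terms with different
#' degrees of freedom. For a 1-df term the adjusted GVIF is the square root
#' of the classical VIF.
#'
#' @param design numeric design matrix WITHOUT the intercept column.
#' @param term_groups named list mapping term label -> column indices (or
#'   names) of `design`; defaults to one group per column.
#' @return data.frame with term, df, gvif, adjusted_gvif.
#' @export
adjusted_gvif <- function(design, term_groups = NULL) {
  X <- as.matrix(design)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient design", call. = FALSE)
  if (is.null(term_groups))
    term_groups <- stats::setNames(as.list(seq_len(ncol(X))), colnames(X))
  R <- stats::cor(X)
  detR <- det(R)
  rows <- lapply(names(term_groups), function(tm) {
    idx <- term_groups[[tm]]
    if (is.character(idx)) idx <- match(idx, colnames(X))
    d <- length(idx)
    if (d == ncol(X)) {
      gv <- 1
    } else {
      gv <- det(R[idx, idx, drop = FALSE]) *
        det(R[-idx, -idx, drop = FALSE]) / detR
    }
    data.frame(term = tm, df = d, gvif = gv,
               adjusted_gvif = gv^(1 / (2 * d)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
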