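#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]. NA p-values are
#' excluded from the family size and propagated as NA.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by the smoother method: pi0(lambda) =
#' mean(p > lambda) / (1 - lambda) over the lambda grid 0.05, 0.10, ...,
#' 0.95, smoothed with a natural cubic spline (df = 3) and evaluated at the
#' largest lambda, clamped to (0, 1]. q-values are pi0 times the
#' Benjamini-Hochberg step-up values. With fewer than 20 p-values the
#' estimate of pi0 is unstable and the function falls back to BH (pi0 = 1)
#' with a warning.
#'
#' @param p numeric p-values.
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional fixed pi0 (forcing pi0 = 1 reproduces BH exactly).
#' @return list with `qvalues` and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  m <- sum(ok)
  if (is.null(pi0)) {
    if (m < 20) {
      warning("fewer than 20 p-values; falling back to BH (pi0 = 1)",
              call. = FALSE)
      pi0 <- 1
    } else {
      pl <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1))
      if (all(pl == 0)) {
        pi0 <- 1 / m  # degenerate: every p tiny
      } else {
        sp <- stats::smooth.spline(lambda, pl, df = 3)
        pi0 <- stats::predict(sp, x = max(lambda))$y
      }
    }
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(pi0 * stats::p.adjust(p[ok], method = "BH"), 1)
  list(qvalues = q, pi0 = pi0)
}
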