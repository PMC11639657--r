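# Equicoordinate rectangle probabilities and quantiles for the central
# multivariate normal / t distribution with correlation matrix R.
#
# Normal rectangle probabilities are computed with the randomized
# quasi-Monte-Carlo algorithm of Genz & Bretz (mvtnorm::pmvnorm).  The
# multivariate t with (possibly non-integer) df is handled as a chi-scale
# mixture of normal rectangles, integrated by Gauss-Legendre quadrature on
# the probability scale: P(|T| <= c) = int_0^1 P(|Z| <= c * s(u)) du with
# s(u) = sqrt(qchisq(u, df)/df).

# Gauss-Legendre nodes/weights on (0, 1); cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: eigen decomposition of the Jacobi matrix on [-1, 1]
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  o <- order(x)
  res <- list(x = (x[o] + 1) / 2, w = w[o] / 2)
  .gl_cache[[key]] <- res
  res
}

# repair an almost-correlation matrix: symmetrize, clip negative
# eigenvalues at 0, renormalize to unit diagonal
.repair_corr <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    lam <- pmax(e$values, 0)
    R <- e$vectors %*% (lam * t(e$vectors))
    s <- sqrt(pmax(diag(R), .Machine$double.eps))
    R <- R / tcrossprod(s)
  }
  diag(R) <- 1
  R
}

# drop coordinates that are perfectly (anti)correlated with an earlier
# one: on a symmetric rectangle |T_a| and |T_b| coincide when |r_ab| = 1
.drop_comonotone <- function(R) {
  q <- nrow(R)
  keep <- rep(TRUE, q)
  for (a in seq_len(q)[-1L])
    for (b in seq_len(a - 1L))
      if (keep[b] && abs(R[a, b]) >= 1 - 1e-10) { keep[a] <- FALSE; break }
  R[keep, keep, drop = FALSE]
}

#' Central equicoordinate rectangle probability
#'
#' Computes `P(|T_1| <= c, ..., |T_q| <= c)` for a centered multivariate
#' normal (`df = Inf`) or t (`df` finite, possibly non-integer) vector with
#' correlation matrix `R`, by randomized quasi-Monte-Carlo integration with
#' a fixed seed, so repeated calls with identical arguments return
#' identical values.
#'
#' @param R correlation matrix (symmetric, unit diagonal; indefiniteness
#'   from rounding is repaired by eigenvalue clipping).
#' @param df degrees of freedom; `Inf` for the normal.
#' @param c non-negative threshold.
#' @param tol target standard error of the integration.
#' @param seed integer seed for the quasi-Monte-Carlo integration; the
#'   ambient RNG state is left untouched.
#' @param mix_nodes quadrature order for the chi-scale mixture used when
#'   `df` is finite.
#' @return Probability in `[0, 1]`.
#' @export
rect_prob <- function(R, df = Inf, c, tol = 5e-4, seed = 20241111L,
                      mix_nodes = 32L) {
  stopifnot(c >= 0, is.matrix(R), nrow(R) == ncol(R))
  if (c == 0) return(0)
  R <- .drop_comonotone(.repair_corr(R))
  q <- nrow(R)
  if (q == 1L) {
    return(if (is.finite(df)) 2 * stats::pt(c, df) - 1
           else 2 * stats::pnorm(c) - 1)
  }
  if (!is.finite(df)) return(.rect_norm(R, c, tol, seed))
  gl <- .gauss_legendre01(mix_nodes)
  s <- sqrt(stats::qchisq(gl$x, df) / df)
  vals <- vapply(s, function(si) .rect_norm(R, c * si, tol, seed), 0)
  min(max(sum(gl$w * vals), 0), 1)
}

.rect_norm <- function(R, c, tol, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  q <- nrow(R)
  p <- mvtnorm::pmvnorm(lower = rep(-c, q), upper = rep(c, q), corr = R,
                        algorithm = mvtnorm::GenzBretz(
                          abseps = tol, maxpts = max(25000L, 5000L * q)))
  min(max(as.numeric(p), 0), 1)
}

#' Two-sided equicoordinate quantile
#'
#' Smallest `c` with `rect_prob(R, df, c) >= 1 - alpha`: the critical value
#' of the single-step maximum test and the half-width multiplier of the
#' simultaneous confidence intervals.  Found by bracketing and bisection on
#' [rect_prob()]; deterministic for fixed `seed`.  For `q = 1` the exact
#' univariate two-sided quantile is returned.
#'
#' @inheritParams rect_prob
#' @param alpha familywise level in (0, 1).
#' @return The quantile `c >= 0`.
#' @examples
#' equicoordinate_quantile(diag(1), Inf, 0.05)   # 1.959964
#' @export
equicoordinate_quantile <- function(R, df = Inf, alpha = 0.05, tol = 1e-5,
                                    seed = 20241111L, mix_nodes = 32L) {
  stopifnot(alpha > 0, alpha < 1)
  R <- .drop_comonotone(.repair_corr(R))
  q <- nrow(R)
  if (q == 1L) {
    return(if (is.finite(df)) stats::qt(1 - alpha / 2, df)
           else stats::qnorm(1 - alpha / 2))
  }
  target <- 1 - alpha
  f <- function(c) rect_prob(R, df, c, tol = tol, seed = seed,
                             mix_nodes = mix_nodes) - target
  lo <- if (is.finite(df)) stats::qt(1 - alpha / 2, df)
        else stats::qnorm(1 - alpha / 2)   # q = 1 lower-bounds the quantile
  hi <- lo + 1
  while (f(hi) < 0 && hi < 50) hi <- hi + 1
  if (f(lo) > 0) lo <- 0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  (lo + hi) / 2
}
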