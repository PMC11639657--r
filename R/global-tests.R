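# Moore-Penrose pseudo-inverse and rank via SVD; rtol relative to the
# largest singular value.
.pinv <- function(A, rtol = 1e-8) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  r <- sum(keep)
  if (r == 0L) return(structure(matrix(0, ncol(A), nrow(A)), rank = 0L))
  structure(s$v[, keep, drop = FALSE] %*%
              (t(s$u[, keep, drop = FALSE]) / s$d[keep]),
            rank = r)
}

# projection onto the row space of C
.row_projection <- function(C, rtol = 1e-8) {
  s <- svd(t(C))
  keep <- s$d > rtol * max(s$d, 0)
  U <- s$u[, keep, drop = FALSE]
  tcrossprod(U)
}

.new_global_test <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "npc_global_test")
}

#' @export
print.npc_global_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(format(unlist(x$df), digits = 5), collapse = ", "),
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Wald-type test for contrasts of relative effects
#'
#' Tests `H0: C p = 0` with the quadratic form
#' `Q_w = g_n * p_hat' C' (C Sigma_hat C')^+ C p_hat`, referred to a
#' chi-squared distribution with `rank(C Sigma_hat C')` degrees of freedom
#' (Moore-Penrose inverse; singular values below `1e-8` of the largest are
#' treated as zero).  Known to be liberal unless sample sizes are large;
#' provided mainly for completeness and comparison.
#'
#' @param fit a [relative_effects()] fit.
#' @param cov an [effect_covariance()] computed under the same scheme.
#' @param C a [contrast_matrix()].
#' @return An object of class `"npc_global_test"` with elements
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
wald_test <- function(fit, cov, C) {
  stopifnot(inherits(fit, "npc_effects"), inherits(cov, "npc_covariance"))
  .wald_quadform(fit$p_hat, cov$sigma_hat, C, cov$g_n, "wald")
}

.wald_quadform <- function(p_hat, sigma, C, g_n, method) {
  Cp <- as.numeric(C %*% p_hat)
  Mhat <- C %*% sigma %*% t(C)
  Minv <- .pinv(Mhat)
  r <- attr(Minv, "rank")
  if (r == 0L) stop("degenerate covariance", call. = FALSE)
  Q <- g_n * as.numeric(Cp %*% Minv %*% Cp)
  .new_global_test(Q, list(df = r),
                   stats::pchisq(Q, df = r, lower.tail = FALSE), method)
}

#' ANOVA-type test for contrasts of relative effects
#'
#' Tests `H0: C p = 0` with
#' `Q_a = g_n * p_hat' M p_hat / tr(M Sigma_hat)`, where `M` is the
#' projection onto the row space of `C`.  The null distribution is
#' approximated by `F(f1, f2)` with the Box-type numerator df
#' `f1 = tr(M Sigma_hat)^2 / tr(M Sigma_hat M Sigma_hat)` and a
#' rank-based denominator df `f2` built from groupwise variances of
#' `global rank - internal rank` residuals, which accounts for the sampling
#' variability of the trace and reduces to the Brunner-Munzel denominator
#' df when `d = 2` and all clusters are singletons.  `approx = "chi2"`
#' uses the asymptotic `chi^2_{f1}/f1` reference instead (known to be
#' liberal in small samples).
#'
#' @inheritParams wald_test
#' @param design,scheme the design and scheme of the fit (needed for the
#'   rank-based denominator df).
#' @param approx `"F"` (default) or `"chi2"`.
#' @return An `"npc_global_test"`; `df` holds `f1` and (for `"F"`) `f2`.
#' @export
anova_test <- function(design, scheme, fit, cov, C, approx = c("F", "chi2")) {
  approx <- match.arg(approx)
  .anova_quadform(design, scheme, fit$p_hat, cov$sigma_hat, C, approx,
                  engine = cov$engine, method = "anova")
}

.anova_quadform <- function(design, scheme, p_hat, sigma, C, approx,
                            engine = NULL, method = "anova") {
  MP <- .row_projection(C)
  MS <- MP %*% sigma
  tr1 <- sum(diag(MS))
  if (tr1 <= 0) stop("degenerate covariance", call. = FALSE)
  Q <- scheme$g_n * as.numeric(p_hat %*% MP %*% p_hat) / tr1
  f1 <- tr1^2 / sum(MS * t(MS))
  if (approx == "chi2") {
    p <- stats::pchisq(f1 * Q, df = f1, lower.tail = FALSE)
    return(.new_global_test(Q, list(f1 = f1, f2 = Inf), p,
                            paste0(method, "_chi2")))
  }
  if (is.null(engine)) engine <- .npc_engine(design, scheme)
  f2 <- .rank_denominator_df(design, scheme, engine)
  p <- stats::pf(Q, f1, f2, lower.tail = FALSE)
  .new_global_test(Q, list(f1 = f1, f2 = f2), p, paste0(method, "_F"))
}

# Denominator df from groupwise rank variances:
# S_i^2 = (n_i-1)^-1 sum_jk omega_ijk (R - R_int - Rbar_i + (M_i+1)/2)^2
# f2 = (sum_i S_i^2/(n-n_i))^2 / sum_i (S_i^2/(n-n_i))^2/(n_i-1)
.rank_denominator_df <- function(design, scheme, eng) {
  og <- design$obs_group; oc <- design$obs_cluster
  Rg <- design$M * eng$Ftheta + 0.5
  Rint <- design$M_i[og] * eng$Fown + 0.5
  w <- scheme$psi[oc] * scheme$omega
  Rbar <- as.numeric(rowsum(w * Rg, og, reorder = TRUE))
  dev <- Rg - Rint - Rbar[og] + (design$M_i[og] + 1) / 2
  S2 <- as.numeric(rowsum(scheme$omega * dev^2, og, reorder = TRUE)) /
    (design$n - 1)
  n <- design$n_total
  u <- S2 / (n - design$n)
  sum(u)^2 / sum(u^2 / (design$n - 1))
}

#' Global tests of equality of the distribution functions
#'
#' Tests the strict null hypothesis `H0F: C F = 0` (all contrasted
#' distribution functions equal) using the same Wald- or ANOVA-type
#' quadratic forms as [wald_test()]/[anova_test()], but with the covariance
#' replaced by its simplification under `H0F`,
#' `g_n * diag(sigma_1^2, ..., sigma_d^2)` from [h0f_variance()].
#'
#' @inheritParams relative_effects
#' @param C a [contrast_matrix()].
#' @param type `"anova"` (default) or `"wald"`.
#' @param approx reference distribution for the ANOVA-type form.
#' @return An `"npc_global_test"`.
#' @export
h0f_test <- function(design, scheme = weight_scheme(design), C,
                     type = c("anova", "wald"), approx = c("F", "chi2")) {
  type <- match.arg(type); approx <- match.arg(approx)
  if (any(design$n < 2L))
    stop("variance requires >=2 clusters per group", call. = FALSE)
  eng <- .npc_engine(design, scheme)
  s2 <- .h0f_sigma2(eng, design, scheme)
  sigmaF <- scheme$g_n * diag(s2, nrow = design$d)
  if (type == "wald")
    .wald_quadform(eng$p_hat, sigmaF, C, scheme$g_n, "wald_H0F")
  else
    .anova_quadform(design, scheme, eng$p_hat, sigmaF, C, approx,
                    engine = eng, method = "anova_H0F")
}
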