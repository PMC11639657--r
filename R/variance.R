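#' Empirical influence vectors of the clustered effect estimator
#'
#' The standardized estimator `sqrt(g_n) * (p_hat - p)` is asymptotically a
#' weighted sum of independent per-cluster vectors `A_ij`.  Their observable
#' counterparts are built from the per-cluster weighted placements
#' `Y_hat_ij^(c) = sum_k omega_ijk F_c_psi(X_ijk)`:
#' component `h` of `A_hat_ij` equals `sum_{s != i} theta_s Y_hat_ij^(s)`
#' when `h = i` and `-theta_i Y_hat_ij^(h)` otherwise.
#'
#' @inheritParams relative_effects
#' @return A `d x K` matrix (`K` = total clusters), column `j` holding
#'   `A_hat_ij` for cluster `j`; attribute `"Y"` carries the `d x K` matrix
#'   of `Y_hat_ij^(c)`.
#' @export
cluster_influence <- function(design, scheme = weight_scheme(design)) {
  eng <- .npc_engine(design, scheme)
  structure(eng$A, Y = eng$Y)
}

#' Covariance estimator of the standardized effect vector
#'
#' Estimates the asymptotic covariance `Sigma` of `sqrt(g_n) (p_hat - p)`
#' by the bias-corrected empirical moment
#' `Sigma_hat = g_n * sum_ij psi_ij^2 / kappa_ij *
#'   (A_hat_ij - Abar_i)(A_hat_ij - Abar_i)'`
#' with `Abar_i = sum_j psi_ij A_hat_ij` and the finite-sample correction
#' `kappa_ij = 1 - 2 psi_ij + sum_j' psi_ij'^2`, which removes the bias
#' introduced by centering at the weighted cluster mean.
#'
#' @inheritParams relative_effects
#' @param fit optionally, the [relative_effects()] fit (to reuse its
#'   computations); must come from the same design and scheme.
#' @return An object of class `"npc_covariance"`: list with `sigma_hat`
#'   (`d x d`, symmetric PSD), `A_hats` (`d x K`), `kappa`, `g_n`.
#' @export
effect_covariance <- function(design, scheme = weight_scheme(design),
                              fit = NULL) {
  if (any(design$n < 2L))
    stop("variance requires >=2 clusters per group", call. = FALSE)
  eng <- if (!is.null(fit) && inherits(fit, "npc_effects")) fit$engine
         else .npc_engine(design, scheme)
  .sigma_from_engine(eng, design, scheme)
}

.sigma_from_engine <- function(eng, design, scheme) {
  cg <- design$cluster_group
  psi <- scheme$psi
  Abar <- t(rowsum(t(eng$A) * psi, cg, reorder = TRUE))  # d x d, col i = Abar_i
  Ac <- eng$A - Abar[, cg, drop = FALSE]
  wcl <- psi^2 / eng$kappa
  sigma <- scheme$g_n * tcrossprod(sweep(Ac, 2L, wcl, `*`), Ac)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(design$groups, design$groups)
  structure(list(sigma_hat = sigma, A_hats = eng$A, Abar = Abar,
                 kappa = eng$kappa, g_n = scheme$g_n, engine = eng),
            class = "npc_covariance")
}

#' @export
print.npc_covariance <- function(x, ...) {
  cat("Covariance of sqrt(g_n)(p_hat - p), g_n =", x$g_n, "\n")
  print(round(x$sigma_hat, 5))
  invisible(x)
}

#' Groupwise variances under equality of distribution functions
#'
#' Under the strict null hypothesis `C F = 0` the covariance of
#' `sqrt(g_n) C p_hat` simplifies to `g_n * C diag(sigma_1^2, ...,
#' sigma_d^2) C'`, where `sigma_i^2` is the variance of the weighted mean
#' of the group-internal cluster placements
#' `Y_hat_ij = sum_k omega_ijk F_i_psi(X_ijk)`.  The unbiased estimator
#' uses the same `psi^2 / kappa` weighting as [effect_covariance()].
#'
#' @inheritParams relative_effects
#' @return Numeric vector `sigma2` of length `d` (named by group).
#' @export
h0f_variance <- function(design, scheme = weight_scheme(design)) {
  if (any(design$n < 2L))
    stop("variance requires >=2 clusters per group", call. = FALSE)
  eng <- .npc_engine(design, scheme)
  .h0f_sigma2(eng, design, scheme)
}

.h0f_sigma2 <- function(eng, design, scheme) {
  oc <- design$obs_cluster; cg <- design$cluster_group
  Yint <- as.numeric(rowsum(scheme$omega * eng$Fown, oc, reorder = TRUE))
  Ybar <- as.numeric(rowsum(scheme$psi * Yint, cg, reorder = TRUE))
  dev2 <- (Yint - Ybar[cg])^2
  s2 <- as.numeric(rowsum(scheme$psi^2 / eng$kappa * dev2, cg,
                          reorder = TRUE))
  names(s2) <- design$groups
  s2
}
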