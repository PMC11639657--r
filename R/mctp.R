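#' Fisher (variance-stabilizing) transformation and its inverse
#'
#' `zeta(x) = 0.5 * log((1 + x)/(1 - x)) = atanh(x)` maps `(-1, 1)` to the
#' real line; back-transformed confidence limits are therefore always
#' inside `(-1, 1)` (range-preserving).
#'
#' @param x numeric in `(-1, 1)` (for `fisher_z`) or any real (for
#'   `fisher_z_inv`).
#' @return Transformed values.
#' @export
fisher_z <- function(x) atanh(x)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(x) tanh(x)

# clip contrast estimates away from +-1 before the Fisher transform
.clip_delta <- function(delta) {
  b <- 1 - 1e-12
  if (any(abs(delta) >= 1)) {
    warning("contrast estimate at the boundary +-1; clipped for the ",
            "Fisher transform")
    delta <- pmin(pmax(delta, -b), b)
  }
  delta
}

#' Satterthwaite-Welch degrees of freedom for a contrast family
#'
#' For each contrast `c_l`, the projected influence values
#' `Lambda_lij = c_l' A_hat_ij` yield groupwise variance components
#' `v_li^2 = sum_j psi_ij^2 / kappa_ij (Lambda_lij - Lambdabar_li)^2`
#' (the same weighting as the covariance estimator) and a Welch-type df
#' `nu_l = (sum_i v_li^2)^2 / sum_i v_li^4 / (n_i - 1)`.  The family df is
#' chosen conservatively as `nu = max(1, min_l nu_l)`; if every `v_li^2`
#' vanishes the df is `Inf` (the t reference degenerates to the normal).
#'
#' @inheritParams relative_effects
#' @param C a [contrast_matrix()].
#' @param A_hats optional `d x K` influence matrix from
#'   [cluster_influence()] / [effect_covariance()]; recomputed if missing.
#' @return The scalar df `nu_hat`, with attribute `"nu_l"` (per-contrast
#'   dfs).
#' @export
satterthwaite_df <- function(design, scheme = weight_scheme(design), C,
                             A_hats = NULL) {
  if (is.null(A_hats)) A_hats <- .npc_engine(design, scheme)$A
  kappa <- {
    psi2g <- as.numeric(rowsum(scheme$psi^2, design$cluster_group,
                               reorder = TRUE))
    1 - 2 * scheme$psi + psi2g[design$cluster_group]
  }
  .satterthwaite(C, A_hats, scheme$psi, kappa, design$cluster_group,
                 design$n)
}

.satterthwaite <- function(C, A, psi, kappa, cg, n) {
  L <- C %*% A                                    # q x K
  Lbar <- t(rowsum(t(L) * psi, cg, reorder = TRUE))  # q x d
  Lc <- L - Lbar[, cg, drop = FALSE]
  v2 <- t(rowsum(t(Lc^2) * (psi^2 / kappa), cg, reorder = TRUE))  # q x d
  tot <- rowSums(v2)
  if (all(tot == 0)) return(structure(Inf, nu_l = rep(Inf, nrow(C))))
  denom <- rowSums(sweep(v2^2, 2L, n - 1, `/`))
  nu_l <- ifelse(denom > 0, tot^2 / denom, Inf)
  structure(max(1, min(nu_l)), nu_l = nu_l)
}

#' Multiple contrast test procedure for clustered relative effects
#'
#' Single-step simultaneous inference on the family of contrasts
#' `delta_l = c_l' p`.  Each statistic `T_l = sqrt(g_n / Upsilon_ll) *
#' c_l' p_hat` (with `Upsilon = C Sigma_hat C'`) is referred jointly to a
#' central multivariate normal or t distribution with estimated correlation
#' `R_hat = cov2cor(Upsilon)`; the common critical value is the two-sided
#' equicoordinate quantile, so the familywise error rate is controlled and
#' compatible simultaneous confidence intervals are obtained by inversion.
#' With `transform = "fisher"` (recommended for small samples together
#' with `approx = "t"`) the statistics and intervals are computed on the
#' variance-stabilized `atanh` scale and back-transformed, making the
#' intervals range-preserving within `(-1, 1)`; the correlation matrix is
#' unchanged by the transformation.  Adjusted p-values are
#' `1 - P(all |T| <= |t_l|)` evaluated under the fitted joint
#' distribution, and the global max-test p-value is their minimum, so the
#' global test rejects exactly when some contrast does (consonance).
#'
#' @inheritParams relative_effects
#' @param C a [contrast_matrix()]; for `transform = "fisher"` entries must
#'   satisfy `|c_li| <= 1`.
#' @param alpha familywise level.
#' @param approx `"t"` (multivariate t with Satterthwaite df, default) or
#'   `"normal"`.
#' @param transform `"fisher"` (default) or `"raw"`.
#' @param sci compute the critical value and simultaneous intervals
#'   (disable to get statistics and adjusted p-values only).
#' @param tol,seed,mix_nodes integration controls passed to
#'   [rect_prob()]/[equicoordinate_quantile()].
#' @return An object of class `"npc_mctp"`: list with the per-contrast
#'   table `comparisons` (estimate, std. dev. `sqrt(Upsilon_ll)`,
#'   statistic, lower/upper SCI, adjusted p-value), `R_hat`, `df`,
#'   `crit`, `global_statistic`, `p_value` (global), `alpha`, tags.
#' @export
mctp <- function(design, scheme = weight_scheme(design), C,
                 alpha = 0.05, approx = c("t", "normal"),
                 transform = c("fisher", "raw"), sci = TRUE,
                 tol = 1e-4, seed = 20241111L, mix_nodes = 32L) {
  approx <- match.arg(approx)
  transform <- match.arg(transform)
  stopifnot(alpha > 0, alpha < 1)
  if (any(design$n < 2L))
    stop("variance requires >=2 clusters per group", call. = FALSE)
  if (transform == "fisher" && any(abs(C) > 1 + 1e-12))
    stop("Fisher-transformed SCIs require |c_li| <= 1", call. = FALSE)

  eng <- .npc_engine(design, scheme)
  cov <- .sigma_from_engine(eng, design, scheme)
  g_n <- scheme$g_n
  delta <- as.numeric(C %*% eng$p_hat)
  Ups <- C %*% cov$sigma_hat %*% t(C)
  dU <- diag(Ups)
  if (any(dU <= 0))
    stop("degenerate variance for contrast ",
         rownames(C)[which(dU <= 0)[1L]], call. = FALSE)
  Rhat <- .repair_corr(Ups / tcrossprod(sqrt(dU)))

  df <- if (approx == "t")
    .satterthwaite(C, eng$A, scheme$psi, cov$kappa, design$cluster_group,
                   design$n)
  else Inf

  T_raw <- sqrt(g_n / dU) * delta
  if (transform == "fisher") {
    dc <- .clip_delta(delta)
    eta <- 1 / (1 - dc^2)
    Gam <- Ups * tcrossprod(eta)             # eta diag scaling
    T_stat <- sqrt(g_n / diag(Gam)) * fisher_z(dc)
  } else {
    Gam <- Ups
    T_stat <- T_raw
  }

  p_adj <- vapply(abs(T_stat), function(tt)
    1 - rect_prob(Rhat, df, tt, tol = tol, seed = seed,
                  mix_nodes = mix_nodes), 0)
  p_adj <- pmin(pmax(p_adj, 0), 1)

  crit <- lower <- upper <- NULL
  if (sci) {
    crit <- equicoordinate_quantile(Rhat, df, alpha, tol = tol, seed = seed,
                                    mix_nodes = mix_nodes)
    hw <- crit * sqrt(diag(Gam) / g_n)
    if (transform == "fisher") {
      lower <- fisher_z_inv(fisher_z(.clip_delta(delta)) - hw)
      upper <- fisher_z_inv(fisher_z(.clip_delta(delta)) + hw)
    } else {
      lower <- delta - hw
      upper <- delta + hw
    }
  }

  comparisons <- data.frame(
    contrast = rownames(C),
    estimate = delta,
    std_dev = sqrt(dU),
    statistic = T_stat,
    lower = if (sci) lower else NA_real_,
    upper = if (sci) upper else NA_real_,
    p_adj = p_adj,
    row.names = NULL
  )
  structure(list(comparisons = comparisons, R_hat = Rhat,
                 df = as.numeric(df), nu_l = attr(df, "nu_l"),
                 crit = crit, global_statistic = max(abs(T_stat)),
                 p_value = min(p_adj), alpha = alpha,
                 approx = approx, transform = transform,
                 p_hat = eng$p_hat, sigma_hat = cov$sigma_hat, g_n = g_n),
            class = "npc_mctp")
}

#' @export
print.npc_mctp <- function(x, ...) {
  cat("Multiple contrast test procedure (", x$approx,
      if (is.finite(x$df)) paste0(", df = ", format(x$df, digits = 4)),
      "; ", x$transform, " scale)\n", sep = "")
  tab <- x$comparisons
  tab[-1L] <- lapply(tab[-1L], round, digits = 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$crit))
    cat("Critical value:", format(x$crit, digits = 5), "\n")
  cat("Global max-test p-value:", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Range-preserving simultaneous confidence intervals
#'
#' Given contrast estimates, their covariance `Upsilon_hat` (of the
#' `sqrt(g_n)`-standardized contrasts) and an equicoordinate critical
#' value, computes Fisher-transformed simultaneous intervals
#' `tanh(atanh(delta_l) -+ crit * sqrt(Gamma_ll / g_n))` with
#' `Gamma = eta Upsilon eta'`, `eta = diag(1/(1 - delta_l^2))`, together
#' with the transformed statistics `T_tilde_l`.
#'
#' @param delta_hat contrast estimates in `(-1, 1)` (values at the
#'   boundary are clipped with a warning).
#' @param Upsilon_hat covariance matrix of the standardized contrasts.
#' @param g_n normalizing rate of the scheme.
#' @param crit equicoordinate critical value.
#' @return List with `lower`, `upper` (inside `(-1, 1)`) and `statistic`.
#' @export
fisher_sci <- function(delta_hat, Upsilon_hat, g_n, crit) {
  delta <- .clip_delta(delta_hat)
  eta <- 1 / (1 - delta^2)
  Gll <- diag(as.matrix(Upsilon_hat)) * eta^2
  z <- fisher_z(delta)
  hw <- crit * sqrt(Gll / g_n)
  list(lower = fisher_z_inv(z - hw), upper = fisher_z_inv(z + hw),
       statistic = sqrt(g_n / Gll) * z)
}

# fast path for simulations: global max-test p-value only (one rectangle
# integral, no quantile search)
.mctp_global_p <- function(design, scheme, C, eng, cov, approx = "t",
                           transform = "fisher", tol = 1e-3,
                           seed = 20241111L, mix_nodes = 24L) {
  delta <- as.numeric(C %*% eng$p_hat)
  Ups <- C %*% cov$sigma_hat %*% t(C)
  dU <- diag(Ups)
  if (any(dU <= 0)) return(NA_real_)
  Rhat <- .repair_corr(Ups / tcrossprod(sqrt(dU)))
  df <- if (approx == "t")
    .satterthwaite(C, eng$A, scheme$psi, cov$kappa, design$cluster_group,
                   design$n)
  else Inf
  if (transform == "fisher") {
    dc <- .clip_delta(delta)
    tmax <- max(abs(sqrt(scheme$g_n) * fisher_z(dc) /
                      sqrt(dU / (1 - dc^2)^2)))
  } else {
    tmax <- max(abs(sqrt(scheme$g_n / dU) * delta))
  }
  1 - rect_prob(Rhat, as.numeric(df), tmax, tol = tol, seed = seed,
                mix_nodes = mix_nodes)
}
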