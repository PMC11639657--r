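#' Normalized empirical distribution function of a weighted point-mass set
#'
#' Evaluates the normalized (mid) EDF, i.e. the average of the left- and
#' right-continuous versions: `F(x) = sum w * (1(v < x) + 0.5 * 1(v == x))`.
#' Ties are resolved by exact equality of the stored values, which is what
#' makes rank methods valid for ordinal and discrete data.
#'
#' @param values numeric vector of support points.
#' @param masses non-negative weights summing to one (equal masses if
#'   omitted).
#' @param x numeric vector of evaluation points.
#' @return `F(x)`, a vector in `[0, 1]`.
#' @examples
#' edf_value(c(1, 3), x = 2)        # 0.5
#' edf_value(5, x = 5)              # 0.5 (mid-value at an atom)
#' edf_value(1:4, x = 3)            # 0.625
#' @export
edf_value <- function(values, masses = NULL, x) {
  if (is.null(masses)) masses <- rep(1 / length(values), length(values))
  stopifnot(length(values) == length(masses), all(masses >= 0),
            abs(sum(masses) - 1) < 1e-8)
  tab <- .edf_table(values, masses)
  .edf_eval(tab, x)
}

# collapse a weighted sample to sorted unique atoms with cumulative mass
.edf_table <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  new <- !duplicated(v)
  vu <- v[new]
  wu <- as.numeric(rowsum(w, cumsum(new)))
  list(v = vu, mass = wu, cum = cumsum(wu))
}

# F(x) = mass(< x) + mass(= x)/2, vectorized over x
.edf_eval <- function(tab, x) {
  idx <- findInterval(x, tab$v)       # number of atoms <= x
  i1 <- pmax(idx, 1L)
  le <- ifelse(idx > 0L, tab$cum[i1], 0)
  eq <- ifelse(idx > 0L & tab$v[i1] == x, tab$mass[i1], 0)
  le - eq / 2
}

# Core computational kernel shared by effects, covariance, ranks and tests.
#
# Returns, for a design/scheme pair:
#   P        d x M matrix, P[c, o] = F_c_psi(x_o)  (group EDF placements)
#   Ftheta   length-M vector, reference EDF at each observation
#   Fown     length-M vector, own-group EDF at each observation
#   p_hat    length-d effect vector
#   Y        d x K matrix, Y[c, j] = sum_k omega * P[c, obs in cluster j]
#   A        d x K matrix of empirical influence vectors A_hat_ij
#   kappa    length-K bias-correction factors
# Everything downstream (Sigma, tests, dfs) is cheap linear algebra on these.
.npc_engine <- function(design, scheme) {
  d <- design$d; x <- design$x
  og <- design$obs_group; oc <- design$obs_cluster
  cg <- design$cluster_group
  K <- design$n_total
  omega <- scheme$omega; psi <- scheme$psi; theta <- scheme$theta

  wobs <- psi[oc] * omega               # F_i_psi mass carried by each obs
  tabs <- lapply(seq_len(d), function(i) {
    sel <- og == i
    .edf_table(x[sel], wobs[sel])
  })
  P <- do.call(rbind, lapply(tabs, .edf_eval, x = x))
  Ftheta <- as.numeric(crossprod(theta, P))
  Fown <- P[cbind(og, seq_along(x))]
  p_hat <- as.numeric(rowsum(wobs * Ftheta, og, reorder = TRUE))

  # per-cluster weighted placements Y[c, j] = Y_hat_ij^(c)
  Y <- t(rowsum(t(P) * omega, oc, reorder = TRUE))
  thetaY <- as.numeric(crossprod(theta, Y))
  A <- -Y * rep(theta[cg], each = d)
  A[cbind(cg, seq_len(K))] <- thetaY - theta[cg] * Y[cbind(cg, seq_len(K))]

  psi2g <- as.numeric(rowsum(psi^2, cg, reorder = TRUE))
  kappa <- 1 - 2 * psi + psi2g[cg]

  list(d = d, P = P, Ftheta = Ftheta, Fown = Fown, p_hat = p_hat,
       Y = Y, A = A, kappa = kappa, tabs = tabs)
}

#' Estimate relative effects in a clustered design
#'
#' Computes the plug-in estimator `p_hat_i = int F_theta d F_i_psi`, the
#' probability that an observation drawn from the weighted reference mixture
#' `F_theta = sum_s theta_s F_s_psi` is smaller than one from group `i`
#' (ties counted half).  `p_hat_i` is a `psi`/`omega`-weighted mean of the
#' reference-EDF placements, so it can be read as a (pseudo-)rank mean:
#' under the `"weighted"` preset it reproduces classical mid-rank
#' estimators, under the `"unweighted"` preset pseudo-rank estimators.
#'
#' @param design a [clustered_design()].
#' @param scheme a [weight_scheme()]; defaults to the unweighted
#'   (pseudo-rank) preset.
#' @return An object of class `"npc_effects"`: list with `p_hat` (named by
#'   group), `placements` (reference-EDF value at each observation),
#'   `scheme`, `design`.
#' @examples
#' dat <- data.frame(group = c("a", "a", "b"), cluster = c(1, 1, 1),
#'                   value = c(1, 3, 4))
#' des <- clustered_design(dat)
#' relative_effects(des)$p_hat   # 0.25, 0.75
#' @export
relative_effects <- function(design, scheme = weight_scheme(design)) {
  eng <- .npc_engine(design, scheme)
  p_hat <- eng$p_hat
  names(p_hat) <- design$groups
  structure(list(p_hat = p_hat, placements = eng$Ftheta,
                 scheme = scheme, design = design, engine = eng),
            class = "npc_effects")
}

#' @export
print.npc_effects <- function(x, ...) {
  cat("Relative effects (", x$scheme$preset, " scheme):\n", sep = "")
  print(round(x$p_hat, 4))
  invisible(x)
}

#' Brute-force oracle for the relative-effect estimator
#'
#' Evaluates `p_hat` by the explicit O(M^2) double sum over all weighted
#' observation pairs rather than via EDF placements.  Intended as an
#' independent cross-check on small designs (M <= a few hundred).
#'
#' @inheritParams relative_effects
#' @return Numeric vector of length `d`.
#' @export
relative_effects_oracle <- function(design, scheme = weight_scheme(design)) {
  d <- design$d; x <- design$x
  og <- design$obs_group; oc <- design$obs_cluster
  w <- scheme$psi[oc] * scheme$omega
  theta <- scheme$theta
  p <- numeric(d)
  for (i in seq_len(d)) {
    xi <- x[og == i]; wi <- w[og == i]
    acc <- 0
    for (s in seq_len(d)) {
      xs <- x[og == s]; ws <- w[og == s]
      cmp <- outer(xs, xi, "<") + 0.5 * outer(xs, xi, "==")
      acc <- acc + theta[s] * as.numeric(ws %*% cmp %*% wi)
    }
    p[i] <- acc
  }
  names(p) <- design$groups
  p
}

#' Global and group-internal (pseudo-)ranks
#'
#' The global rank of an observation is `R = M * F_theta(x) + 1/2` where
#' `F_theta` is the scheme's reference EDF and `M` the total number of
#' observations; under the `"weighted"` preset these are the classical
#' mid-ranks of the pooled sample, under the `"unweighted"` preset
#' pseudo-ranks.  The internal rank is `R_int = M_i * F_i_psi(x) + 1/2`,
#' ranking the observation among the `M_i` observations of its own group
#' (under the group's cluster weighting).
#'
#' @inheritParams relative_effects
#' @return List with numeric vectors `global` and `internal` (design
#'   order).
#' @export
cluster_ranks <- function(design, scheme = weight_scheme(design)) {
  eng <- .npc_engine(design, scheme)
  list(global = design$M * eng$Ftheta + 0.5,
       internal = design$M_i[design$obs_group] * eng$Fown + 0.5)
}
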