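# Simulation harness: marginals, correlation structures, imbalance
# constructions and rejection-rate studies for the three test procedures.

#' Within-cluster correlation matrices
#'
#' `"none"` gives the identity; `"homogeneous"` an equicorrelation matrix
#' with off-diagonal `rho_max`; `"heterogeneous"` the outer product
#' `rho r r'` of a vector `r` of U(rho_min, rho_max) draws with the
#' diagonal reset to one (positive semidefinite by construction for
#' `rho` values in `[0, 1)`).
#'
#' @param structure `"none"`, `"homogeneous"` or `"heterogeneous"`.
#' @param m cluster size.
#' @param rho_min,rho_max correlation bounds, `0 <= rho_min <= rho_max < 1`.
#' @return An `m x m` correlation matrix.
#' @export
sim_correlation <- function(structure = c("none", "homogeneous",
                                          "heterogeneous"),
                            m, rho_min = 0, rho_max = 0) {
  structure <- match.arg(structure)
  if (rho_max >= 1 || rho_min < 0 || rho_min > rho_max)
    stop("need 0 <= rho_min <= rho_max < 1", call. = FALSE)
  if (m == 1L || structure == "none") return(diag(m))
  if (structure == "homogeneous") {
    R <- matrix(rho_max, m, m); diag(R) <- 1
    return(R)
  }
  r <- stats::runif(m, rho_min, rho_max)
  R <- tcrossprod(r)
  diag(R) <- 1
  R
}

#' Cluster sizes under the study's imbalance constructions
#'
#' `"none"`: all clusters of size `base_m`.  `"mild"`: each size drawn
#' uniformly from `max(base_m - 3, 2), ..., base_m + 3`.  `"severe"`:
#' `n_i - 2` clusters of size `base_m`, one of size 2 and one of size 15,
#' in random order.
#'
#' @param imbalance `"none"`, `"mild"` or `"severe"`.
#' @param base_m nominal cluster size.
#' @param n_i number of clusters.
#' @return Integer vector of `n_i` sizes (>= 2 under mild/severe).
#' @export
sim_cluster_sizes <- function(imbalance = c("none", "mild", "severe"),
                              base_m, n_i) {
  imbalance <- match.arg(imbalance)
  if (imbalance == "none") return(rep.int(base_m, n_i))
  if (imbalance == "mild") {
    pool <- seq.int(max(base_m - 3L, 2L), base_m + 3L)
    return(pool[sample.int(length(pool), n_i, replace = TRUE)])
  }
  if (n_i < 2L) stop("severe imbalance needs n_i >= 2", call. = FALSE)
  sample(c(rep.int(base_m, n_i - 2L), 2L, 15L))
}

#' Group sizes under the study's imbalance constructions
#'
#' Mirrors [sim_cluster_sizes()] at the group level: `"mild"` draws each
#' `n_i` from `base_n - 3, ..., base_n + 3`; `"severe"` sets one group to
#' 8, one to 25 and the rest to `base_n`.
#'
#' @inheritParams sim_cluster_sizes
#' @param base_n nominal group size (clusters per group).
#' @param d number of groups.
#' @return Integer vector of `d` group sizes.
#' @export
sim_group_sizes <- function(imbalance = c("none", "mild", "severe"),
                            base_n, d) {
  imbalance <- match.arg(imbalance)
  if (imbalance == "none") return(rep.int(base_n, d))
  if (imbalance == "mild") {
    pool <- seq.int(max(base_n - 3L, 2L), base_n + 3L)
    return(pool[sample.int(length(pool), d, replace = TRUE)])
  }
  if (d < 2L) stop("severe imbalance needs d >= 2", call. = FALSE)
  sample(c(8L, 25L, rep.int(base_n, d - 2L)))
}

#' Simulation model specification
#'
#' Bundles the marginal family with its group-wise parameters, the
#' within-cluster correlation structure, the imbalance constructions and
#' the weighting scheme of a simulation study.  Under the null (`r = 0`)
#' all groups share one marginal; under the alternative the parameters
#' shift with the factor `r`:
#' normal `mu_i = r * i`, `sd_i = 0.7 + 0.1 * i`;
#' beta `alpha_i = 2 + r * (i - 1)`, `beta_i = 4 - r * (i - 1)`;
#' poisson `lambda_i = 5 + r * i`; binomial fixed at `Bin(5, 0.6)`.
#' For the type-I error models the marginals are
#' normal `N(0, sd_i)` (with `sd_i = 1`, or `0.1 * i^2` if
#' `heteroscedastic`), `Beta(2, 5)`, `Pois(5)` and `Bin(5, 0.6)`.
#'
#' @param marginal `"normal"`, `"beta"`, `"poisson"` or `"binomial"`.
#' @param r shift factor (`0` = null hypothesis configuration).
#' @param correlation `"none"`, `"homogeneous"` or `"heterogeneous"`.
#' @param rho_min,rho_max correlation bounds.
#' @param imbalance imbalance applied to both group and cluster sizes.
#' @param scheme `"unweighted"` (pseudo-rank) or `"weighted"` (rank).
#' @param heteroscedastic use `sd_i = 0.1 * i^2` for the null normal
#'   model.
#' @return An object of class `"sim_model"`.
#' @export
sim_model <- function(marginal = c("normal", "beta", "poisson", "binomial"),
                      r = 0,
                      correlation = c("none", "homogeneous",
                                      "heterogeneous"),
                      rho_min = 0, rho_max = 0,
                      imbalance = c("none", "mild", "severe"),
                      scheme = c("unweighted", "weighted"),
                      heteroscedastic = FALSE) {
  structure(list(marginal = match.arg(marginal), r = r,
                 correlation = match.arg(correlation),
                 rho_min = rho_min, rho_max = rho_max,
                 imbalance = match.arg(imbalance),
                 scheme = match.arg(scheme),
                 heteroscedastic = heteroscedastic),
            class = "sim_model")
}

# marginal quantile function for group i under model
.marginal_quantile <- function(model, i) {
  r <- model$r
  switch(model$marginal,
    normal = {
      if (r > 0) {
        mu <- r * i; sd <- 0.7 + 0.1 * i
      } else {
        mu <- 0; sd <- if (model$heteroscedastic) 0.1 * i^2 else 1
      }
      function(u) stats::qnorm(u, mean = mu, sd = sd)
    },
    beta = {
      a <- 2 + r * (i - 1); b <- if (r > 0) 4 - r * (i - 1) else 5
      if (a <= 0 || b <= 0) stop("invalid beta parameters", call. = FALSE)
      function(u) stats::qbeta(u, a, b)
    },
    poisson = {
      lam <- 5 + r * i * (r > 0)
      function(u) stats::qpois(u, lam)
    },
    binomial = function(u) stats::qbinom(u, 5, 0.6)
  )
}

#' Draw one clustered dataset from a simulation model
#'
#' Within each cluster the joint distribution is a Gaussian copula: a
#' multivariate normal draw with the cluster's correlation matrix is
#' mapped through the standard normal CDF to uniforms and then through
#' the group's marginal quantile function, so all observations of a
#' cluster share the marginal while being dependent.  (Normal marginals
#' are thereby generated exactly.)
#'
#' @param model a [sim_model()].
#' @param d number of groups.
#' @param n_vec clusters per group (length `d`).
#' @param sizes list of length `d` of cluster-size vectors.
#' @return A [clustered_design()].
#' @export
sim_clustered_data <- function(model, d, n_vec, sizes) {
  stopifnot(length(n_vec) == d, length(sizes) == d)
  xs <- vector("list", d); gs <- vector("list", d); cs <- vector("list", d)
  for (i in seq_len(d)) {
    qf <- .marginal_quantile(model, i)
    mi <- sizes[[i]]
    xi <- vector("list", n_vec[i])
    for (j in seq_len(n_vec[i])) {
      m <- mi[j]
      R <- sim_correlation(model$correlation, m, model$rho_min,
                           model$rho_max)
      z <- as.numeric(crossprod(chol(R), stats::rnorm(m)))
      xi[[j]] <- qf(stats::pnorm(z))
    }
    xs[[i]] <- unlist(xi)
    gs[[i]] <- rep.int(i, sum(mi))
    cs[[i]] <- rep.int(seq_len(n_vec[i]), mi)
  }
  clustered_design(data.frame(group = unlist(gs),
                              cluster = unlist(cs),
                              value = unlist(xs)),
                   group_order = as.character(seq_len(d)))
}

#' Rejection-rate study for the three test procedures
#'
#' For each replicate a dataset is drawn from `model`, analysed with the
#' Wald-type test, the ANOVA-type test with F approximation and the MCTP
#' (multivariate t, Fisher transform) for the chosen contrast family, and
#' the rejections at level `alpha` are recorded.  With `r = 0` in the
#' model the proportions estimate the type-I error rate, otherwise power.
#' Fully reproducible from `seed`.
#'
#' @param model a [sim_model()].
#' @param d number of groups.
#' @param n_base nominal clusters per group.
#' @param base_m nominal cluster size.
#' @param reps number of Monte-Carlo replicates (>= 100).
#' @param alpha nominal level.
#' @param seed integer seed.
#' @param contrast contrast family used by all tests (`"centering"`,
#'   `"tukey"` or `"dunnett"`).
#' @param tests subset of `c("wald", "anova_f", "mctp")` to run.
#' @return An object of class `"npc_study"`: data frame with one row per
#'   test (`rejection` proportion, `mc_se`, `reps`) plus the
#'   configuration as attributes.
#' @export
run_study <- function(model, d, n_base, base_m, reps = 2000, alpha = 0.05,
                      seed = 1L,
                      contrast = c("centering", "tukey", "dunnett"),
                      tests = c("wald", "anova_f", "mctp")) {
  contrast <- match.arg(contrast)
  tests <- match.arg(tests, several.ok = TRUE)
  if (reps < 100) stop("need reps >= 100", call. = FALSE)
  C <- contrast_matrix(contrast, d)
  rej <- matrix(0, reps, 3L,
                dimnames = list(NULL, c("wald", "anova_f", "mctp")))
  set.seed(seed)
  for (b in seq_len(reps)) {
    n_vec <- sim_group_sizes(model$imbalance, n_base, d)
    sizes <- lapply(n_vec, function(ni)
      sim_cluster_sizes(model$imbalance, base_m, ni))
    des <- sim_clustered_data(model, d, n_vec, sizes)
    sch <- weight_scheme(des, model$scheme)
    eng <- .npc_engine(des, sch)
    cov <- .sigma_from_engine(eng, des, sch)
    if ("wald" %in% tests) {
      q <- tryCatch(.wald_quadform(eng$p_hat, cov$sigma_hat, C, sch$g_n,
                                   "wald")$p_value,
                    error = function(e) NA_real_)
      rej[b, "wald"] <- !is.na(q) && q <= alpha
    }
    if ("anova_f" %in% tests) {
      q <- tryCatch(.anova_quadform(des, sch, eng$p_hat, cov$sigma_hat, C,
                                    "F", engine = eng)$p_value,
                    error = function(e) NA_real_)
      rej[b, "anova_f"] <- !is.na(q) && q <= alpha
    }
    if ("mctp" %in% tests) {
      p <- .mctp_global_p(des, sch, C, eng, cov)
      rej[b, "mctp"] <- !is.na(p) && p <= alpha
    }
  }
  pr <- colMeans(rej)[tests]
  out <- data.frame(test = tests, rejection = as.numeric(pr),
                    mc_se = sqrt(pr * (1 - pr) / reps),
                    reps = reps, row.names = NULL)
  structure(out, class = c("npc_study", "data.frame"),
            config = list(model = model, d = d, n_base = n_base,
                          base_m = base_m, alpha = alpha, seed = seed,
                          contrast = contrast))
}

#' @export
print.npc_study <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Rejection-rate study: d =", cfg$d, ", n_i =", cfg$n_base,
      ", m =", cfg$base_m, ", alpha =", cfg$alpha,
      ", r =", cfg$model$r, "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
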