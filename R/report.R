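#' Full analysis workflow for a clustered design
#'
#' Runs the complete inference pipeline: relative effects with their
#' standard deviations and simultaneous confidence intervals, the
#' per-contrast MCTP table, and the global Wald-type, ANOVA-type and
#' MCTP max-test p-values.
#'
#' Per-group simultaneous intervals are computed with the same MCTP
#' machinery applied to the centered effects `p_i - 1/2` (identity
#' "contrasts", Fisher-transformed when `transform = "fisher"`) and
#' shifted back by 1/2, so all `d` group intervals hold jointly at level
#' `1 - alpha`.  The reported per-group standard deviation is
#' `sqrt(Sigma_hat_ii)`, the standard deviation of the
#' `sqrt(g_n)`-standardized effect estimator.
#'
#' @inheritParams relative_effects
#' @param C a [contrast_matrix()] (default: Tukey-type all-pairwise).
#' @param alpha significance level.
#' @param approx,transform MCTP approximation and interval scale, see
#'   [mctp()].
#' @param h0f additionally test the strict null hypothesis of equal
#'   distribution functions.
#' @param seed integration seed for reproducible critical values.
#' @return An object of class `"npc_report"`: list of data frames
#'   `groups`, `comparisons`, `global`, plus the fitted pieces.
#' @export
npc_analyze <- function(design, scheme = weight_scheme(design),
                        C = contrast_matrix("tukey", design$d),
                        alpha = 0.05, approx = c("t", "normal"),
                        transform = c("fisher", "raw"), h0f = FALSE,
                        seed = 20241111L) {
  approx <- match.arg(approx)
  transform <- match.arg(transform)
  fit <- relative_effects(design, scheme)
  cov <- effect_covariance(design, scheme, fit)
  mc <- mctp(design, scheme, C, alpha = alpha, approx = approx,
             transform = transform, seed = seed)
  wt <- wald_test(fit, cov, C)
  at <- anova_test(design, scheme, fit, cov, C)

  # joint intervals for the d effects via the identity "contrast" family
  # on the centered effects p_i - 1/2
  eng <- fit$engine
  Rg <- .repair_corr(stats::cov2cor(cov$sigma_hat))
  dfg <- if (approx == "t")
    .satterthwaite(diag(design$d), eng$A, scheme$psi, cov$kappa,
                   design$cluster_group, design$n)
  else Inf
  critg <- equicoordinate_quantile(Rg, as.numeric(dfg), alpha, seed = seed)
  deltag <- fit$p_hat - 0.5
  if (transform == "fisher") {
    sci <- fisher_sci(deltag, cov$sigma_hat, scheme$g_n, critg)
    glo <- sci$lower + 0.5; ghi <- sci$upper + 0.5
  } else {
    hw <- critg * sqrt(diag(cov$sigma_hat) / scheme$g_n)
    glo <- fit$p_hat - hw; ghi <- fit$p_hat + hw
  }
  groups <- data.frame(group = design$groups,
                       estimator = as.numeric(fit$p_hat),
                       std_dev = sqrt(diag(cov$sigma_hat)),
                       lower = glo, upper = ghi, row.names = NULL)

  global <- data.frame(
    method = c("wald", "anova_F", "mctp_max"),
    statistic = c(wt$statistic, at$statistic, mc$global_statistic),
    df1 = c(wt$df$df, at$df$f1, mc$df),
    df2 = c(NA, at$df$f2, NA),
    p_value = c(wt$p_value, at$p_value, mc$p_value), row.names = NULL)
  if (h0f) {
    hw2 <- h0f_test(design, scheme, C, type = "wald")
    ha2 <- h0f_test(design, scheme, C, type = "anova")
    global <- rbind(global, data.frame(
      method = c("wald_H0F", "anova_H0F_F"),
      statistic = c(hw2$statistic, ha2$statistic),
      df1 = c(hw2$df$df, ha2$df$f1),
      df2 = c(NA, ha2$df$f2),
      p_value = c(hw2$p_value, ha2$p_value)))
  }
  structure(list(groups = groups, comparisons = mc$comparisons,
                 global = global, effects = fit, covariance = cov,
                 mctp = mc, alpha = alpha, scheme = scheme),
            class = "npc_report")
}

#' @export
print.npc_report <- function(x, digits = 2, ...) {
  cat("Relative effects (", x$scheme$preset, " scheme), ",
      100 * (1 - x$alpha), "% simultaneous intervals:\n", sep = "")
  g <- x$groups; g[-1L] <- lapply(g[-1L], round, digits = digits)
  print(g, row.names = FALSE)
  cat("\nContrasts (", x$mctp$transform, " SCIs, ", x$mctp$approx,
      " approximation):\n", sep = "")
  cmp <- x$comparisons; cmp[-1L] <- lapply(cmp[-1L], round, digits = digits)
  print(cmp, row.names = FALSE)
  cat("\nGlobal tests:\n")
  gl <- x$global
  gl$statistic <- round(gl$statistic, 3)
  gl$df1 <- round(gl$df1, 2); gl$df2 <- round(gl$df2, 2)
  gl$p_value <- round(gl$p_value, 4)
  print(gl, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to CSV files
#'
#' Writes `groups.csv`, `comparisons.csv` and `global.csv` (full
#' precision) plus a human-readable `report.txt` into `dir`.
#'
#' @param report an [npc_analyze()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "npc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$global, file.path(dir, "global.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report, digits = 4)
  cat("\nScheme g_n:", report$scheme$g_n,
      "\nMCTP df:", report$mctp$df,
      "\nMCTP critical value:", report$mctp$crit, "\n")
  cat("\nEstimated contrast correlation matrix:\n")
  print(round(report$mctp$R_hat, 4))
  invisible(dir)
}

#' Generate small clustered-data fixture files
#'
#' `"toy"` writes the three-observation two-group worked example
#' (effects 0.25/0.75).  `"moyamoya_like"` writes a *synthetic* analogue
#' of a bilateral ordinal grading study: 4 groups with 12, 9, 21 and 6
#' clusters (patients) of size 2 (hemispheres) and ordinal grades 1-3
#' generated from a Gaussian copula with within-cluster correlation 0.5;
#' it mimics the structure, not the values, of any real cohort.
#' `"model_table3"` writes one draw of a named type-I error simulation
#' model (`model` argument, e.g. `sim_model("beta", correlation =
#' "homogeneous", rho_max = 0.35)`).
#'
#' @param kind `"toy"`, `"moyamoya_like"` or `"model_table3"`.
#' @param path output CSV path.
#' @param seed integer seed (ignored for the deterministic toy fixture).
#' @param model,d,n_base,base_m configuration for `"model_table3"`.
#' @return `path`, invisibly.
#' @export
fixture_clustered_csv <- function(kind = c("toy", "moyamoya_like",
                                           "model_table3"),
                                  path, seed = 1L,
                                  model = sim_model("normal"), d = 3,
                                  n_base = 12, base_m = 4) {
  kind <- match.arg(kind)
  if (kind == "toy") {
    dat <- data.frame(group = c("1", "1", "2"), cluster = c("1", "1", "1"),
                      value = c(1, 3, 4))
  } else if (kind == "moyamoya_like") {
    set.seed(seed)
    n_vec <- c(12L, 9L, 21L, 6L)
    mu <- c(0.35, -0.3, 0, 0.1)     # latent group shifts, synthetic
    rows <- list()
    for (i in 1:4) {
      for (j in seq_len(n_vec[i])) {
        z <- mu[i] + as.numeric(crossprod(chol(matrix(c(1, .5, .5, 1), 2)),
                                          stats::rnorm(2)))
        grade <- findInterval(z, c(-0.45, 0.85)) + 1L   # grades 1..3
        rows[[length(rows) + 1L]] <-
          data.frame(group = i, cluster = paste0("p", i, "_", j),
                     value = grade)
      }
    }
    dat <- do.call(rbind, rows)
  } else {
    set.seed(seed)
    n_vec <- sim_group_sizes(model$imbalance, n_base, d)
    sizes <- lapply(n_vec, function(ni)
      sim_cluster_sizes(model$imbalance, base_m, ni))
    des <- sim_clustered_data(model, d, n_vec, sizes)
    dat <- data.frame(group = des$groups[des$obs_group],
                      cluster = des$cluster_id[des$obs_cluster],
                      value = des$x)
  }
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the studies described in a YAML configuration
#'
#' Each entry of the YAML list names a configuration with fields
#' `marginal`, `r`, `correlation`, `rho_min`, `rho_max`, `imbalance`,
#' `scheme`, `heteroscedastic`, `d`, `n_base` (clusters per group),
#' `base_m` (cluster size), `alpha`, `contrast` (all optional except `d`,
#' `n_base`, `base_m`); results are returned as one data frame with a
#' `config` column.
#'
#' @param config_path YAML file path.
#' @param reps replicates per configuration.
#' @param seed root seed; configuration `k` uses `seed + k - 1`.
#' @return Data frame of stacked [run_study()] results.
#' @export
run_study_config <- function(config_path, reps = 2000, seed = 1L) {
  cfgs <- yaml::read_yaml(config_path)
  if (!length(cfgs)) stop("empty study configuration", call. = FALSE)
  out <- list()
  for (k in seq_along(cfgs)) {
    cf <- cfgs[[k]]
    nm <- if (!is.null(names(cfgs)[k]) && nzchar(names(cfgs)[k]))
      names(cfgs)[k] else paste0("config", k)
    model <- sim_model(
      marginal = cf$marginal %||% "normal",
      r = cf$r %||% 0,
      correlation = cf$correlation %||% "none",
      rho_min = cf$rho_min %||% 0, rho_max = cf$rho_max %||% 0,
      imbalance = cf$imbalance %||% "none",
      scheme = cf$scheme %||% "unweighted",
      heteroscedastic = isTRUE(cf$heteroscedastic))
    if (is.null(cf$d) || is.null(cf$n_base) || is.null(cf$base_m))
      stop("configuration '", nm, "' needs fields d, n_base, base_m",
           call. = FALSE)
    res <- run_study(model, d = cf$d, n_base = cf$n_base,
                     base_m = cf$base_m,
                     reps = reps, alpha = cf$alpha %||% 0.05,
                     seed = seed + k - 1L,
                     contrast = cf$contrast %||% "centering")
    res$config <- nm
    out[[k]] <- as.data.frame(res)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
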