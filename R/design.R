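#' Build a clustered design from long-format data
#'
#' Organises one-row-per-observation data into `d` independent samples
#' (groups), each consisting of `n_i` clusters of possibly correlated
#' replicate observations.  Observations within a cluster share a
#' `(group, cluster)` pair; clusters are assumed independent, observations
#' within a cluster may be arbitrarily dependent.  Values may be metric,
#' ordinal (numeric codes; only their ordering is used downstream) or
#' dichotomous.
#'
#' @param data a data frame in long format.
#' @param group,cluster,value names of the columns holding the group label,
#'   the cluster identifier (unique within a group; the same identifier in
#'   different groups denotes different, independent clusters) and the
#'   numeric observation.
#' @param group_order optional character vector fixing the order of the
#'   groups; defaults to order of first appearance.  All downstream output
#'   (effects, contrasts, tables) indexes groups in this order.
#'
#' @return An object of class `"clustered_design"`: a list with elements
#'   `groups` (labels), `d`, `n` (clusters per group), `m` (cluster sizes),
#'   `M_i` (observations per group), `M`, `n_total` (total clusters),
#'   `x` (observation values), `obs_group`, `obs_cluster`, `cluster_group`
#'   (integer index vectors) and `cluster_id` (original identifiers).
#' @examples
#' d <- data.frame(group   = c("a", "a", "b"),
#'                 cluster = c("s1", "s1", "s2"),
#'                 value   = c(1, 3, 4))
#' clustered_design(d)
#' @export
clustered_design <- function(data, group = "group", cluster = "cluster",
                             value = "value", group_order = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(group, cluster, value))
    if (!col %in% names(data))
      stop("column '", col, "' not found in `data`", call. = FALSE)
  g <- as.character(data[[group]])
  cl <- as.character(data[[cluster]])
  x <- as.numeric(data[[value]])
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(is.na(x) | !is.finite(x))[1L]
    stop("non-finite value in row ", bad, call. = FALSE)
  }
  groups <- if (is.null(group_order)) unique(g) else as.character(group_order)
  if (!setequal(groups, unique(g)) || anyDuplicated(groups))
    if (!is.null(group_order))
      stop("`group_order` must be a permutation of the observed group labels",
           call. = FALSE)
  if (length(groups) < 2L)
    stop("need >=2 groups", call. = FALSE)

  og <- match(g, groups)
  # cluster index: unique within (group, cluster id), ordered by group then
  # first appearance
  key <- paste(og, cl, sep = "\r")
  ukey <- unique(key[order(og, match(key, unique(key)))])
  oc <- match(key, ukey)
  ord <- order(oc)
  x <- x[ord]; og <- og[ord]; oc <- oc[ord]
  cluster_group <- vapply(seq_along(ukey), function(k) og[oc == k][1L], 1L)
  cluster_id <- sub("^[0-9]+\r", "", ukey)
  m <- tabulate(oc, nbins = length(ukey))
  n <- tabulate(cluster_group, nbins = length(groups))
  M_i <- vapply(seq_along(groups), function(i) sum(m[cluster_group == i]), 0)

  out <- structure(list(
    groups = groups, d = length(groups),
    n = n, m = m, M_i = M_i, M = sum(m), n_total = sum(n),
    x = x, obs_group = og, obs_cluster = oc,
    cluster_group = cluster_group, cluster_id = cluster_id
  ), class = "clustered_design")
  stopifnot(out$M == length(x), all(out$n >= 1L), all(out$m >= 1L))
  out
}

#' @export
print.clustered_design <- function(x, ...) {
  cat("Clustered design:", x$d, "groups,", x$n_total, "clusters,",
      x$M, "observations\n")
  tab <- data.frame(group = x$groups, clusters = x$n, observations = x$M_i)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read a clustered design from a long-format CSV file
#'
#' Expects a header `group,cluster,value` (or the column names passed on to
#' [clustered_design()]), UTF-8, one row per observation.
#'
#' @param path path to the CSV file.
#' @inheritParams clustered_design
#' @return A [clustered_design()] object.
#' @export
read_clustered_csv <- function(path, group = "group", cluster = "cluster",
                               value = "value", group_order = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  clustered_design(dat, group = group, cluster = cluster, value = value,
                   group_order = group_order)
}

#' Weighting scheme for clustered relative effects
#'
#' A scheme bundles the within-cluster weights `omega` (per observation,
#' summing to one within each cluster), the cluster weights `psi` (per
#' cluster, summing to one within each group), the reference-distribution
#' weights `theta` (per group, summing to one) and the normalizing rate
#' `g_n` of the standardized estimator.
#'
#' Presets:
#' \describe{
#' \item{`"unweighted"`}{`omega = 1/m_ij`, `psi = 1/n_i`, `theta = 1/d`,
#'   `g_n = n` (total clusters).  Effects relative to the unweighted mean
#'   distribution; computable via pseudo-ranks.  Recommended default, as
#'   the resulting effects do not depend on sample-size allocation.}
#' \item{`"weighted"`}{`omega = 1/m_ij`, `psi = m_ij/M_i`,
#'   `theta = M_i/M`, `g_n = M` (total observations).  Effects relative to
#'   the pooled distribution; computable via classical mid-ranks.}
#' }
#' Custom weights (e.g. variance-based or hierarchical `theta`) may be
#' supplied directly and are validated against the design.
#'
#' @param design a [clustered_design()].
#' @param preset `"unweighted"`, `"weighted"` or `"custom"`.
#' @param omega,psi,theta,g_n custom weights; for `preset = "custom"` any
#'   subset may be given, the rest defaults to the unweighted preset.
#'   `omega` is one value per observation (in design order), `psi` one per
#'   cluster, `theta` one per group.
#' @return An object of class `"weight_scheme"`.
#' @export
weight_scheme <- function(design,
                          preset = c("unweighted", "weighted", "custom"),
                          omega = NULL, psi = NULL, theta = NULL, g_n = NULL) {
  stopifnot(inherits(design, "clustered_design"))
  preset <- match.arg(preset)
  m <- design$m; oc <- design$obs_cluster; cg <- design$cluster_group
  if (preset == "unweighted") {
    omega <- 1 / m[oc]
    psi <- 1 / design$n[cg]
    theta <- rep(1 / design$d, design$d)
    g_n <- design$n_total
  } else if (preset == "weighted") {
    omega <- 1 / m[oc]
    psi <- m / design$M_i[cg]
    theta <- design$M_i / design$M
    g_n <- design$M
  } else {
    if (is.null(omega)) omega <- 1 / m[oc]
    if (is.null(psi)) psi <- 1 / design$n[cg]
    if (is.null(theta)) theta <- rep(1 / design$d, design$d)
    if (is.null(g_n)) g_n <- design$n_total
  }
  .check_weights(design, omega, psi, theta, g_n)
  structure(list(preset = preset, omega = omega, psi = psi, theta = theta,
                 g_n = g_n),
            class = "weight_scheme")
}

# normalization/non-negativity invariants, tolerance 1e-12
.check_weights <- function(design, omega, psi, theta, g_n) {
  tol <- 1e-12
  stopifnot(length(omega) == design$M, length(psi) == design$n_total,
            length(theta) == design$d, length(g_n) == 1L, g_n > 0)
  if (any(omega < -tol))
    stop("negative omega weight at observation ", which(omega < -tol)[1L],
         call. = FALSE)
  if (any(psi < -tol))
    stop("negative psi weight at cluster ", which(psi < -tol)[1L],
         call. = FALSE)
  if (any(theta < -tol))
    stop("negative theta weight at group ", which(theta < -tol)[1L],
         call. = FALSE)
  so <- rowsum(omega, design$obs_cluster)
  if (any(abs(so - 1) > 1e-8))
    stop("omega weights do not sum to 1 in cluster ",
         which(abs(so - 1) > 1e-8)[1L], call. = FALSE)
  sp <- rowsum(psi, design$cluster_group)
  if (any(abs(sp - 1) > 1e-8))
    stop("psi weights do not sum to 1 in group ",
         which(abs(sp - 1) > 1e-8)[1L], call. = FALSE)
  if (abs(sum(theta) - 1) > 1e-8)
    stop("theta weights do not sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme (", x$preset, "): theta = ",
      paste(signif(x$theta, 4), collapse = ", "),
      "; g_n = ", x$g_n, "\n", sep = "")
  invisible(x)
}

#' Contrast matrices for relative-effect hypotheses
#'
#' Builds a `q x d` contrast matrix `C` with zero row sums and full row
#' rank for the null hypothesis `C p = 0`.
#'
#' @param kind `"centering"` (`I_d - 1/d J_d`, global equality of all
#'   effects), `"dunnett"` (many-to-one comparisons against `control`) or
#'   `"tukey"` (all pairwise comparisons).
#' @param d number of groups (>= 2).
#' @param control index of the control group for Dunnett contrasts.
#' @return A numeric matrix of class `"contrast_matrix"` with informative
#'   row names.
#' @examples
#' contrast_matrix("tukey", 4)
#' @export
contrast_matrix <- function(kind = c("centering", "dunnett", "tukey"), d,
                            control = 1L) {
  kind <- match.arg(kind)
  if (d < 2) stop("need d >= 2", call. = FALSE)
  if (kind == "centering") {
    C <- diag(d) - matrix(1 / d, d, d)
    rownames(C) <- paste0(seq_len(d), "-mean")
  } else if (kind == "dunnett") {
    if (control < 1 || control > d) stop("invalid control group", call. = FALSE)
    others <- setdiff(seq_len(d), control)
    C <- matrix(0, d - 1L, d)
    C[cbind(seq_len(d - 1L), others)] <- 1
    C[, control] <- -1
    rownames(C) <- paste0(others, "-", control)
  } else {
    pairs <- utils::combn(d, 2L)
    C <- matrix(0, ncol(pairs), d)
    C[cbind(seq_len(ncol(pairs)), pairs[2L, ])] <- 1
    C[cbind(seq_len(ncol(pairs)), pairs[1L, ])] <- -1
    rownames(C) <- paste0(pairs[2L, ], "-", pairs[1L, ])
  }
  as_contrast_matrix(C, kind = kind, check_rank = kind == "dunnett")
}

#' Validate a user-supplied contrast matrix
#'
#' @param C a numeric `q x d` matrix; every row must sum to zero
#'   (tolerance 1e-10).  For use with Fisher-transformed simultaneous
#'   intervals entries should satisfy `|c_li| <= 1`.
#' @param kind tag describing the contrast family.
#' @param check_rank warn when the matrix is not of full row rank.  The
#'   built-in centering and Tukey families are deliberately rank `d - 1`
#'   (the quadratic tests use only the row space, the MCTP tests each row)
#'   and skip this check.
#' @return `C` with class `"contrast_matrix"`.
#' @export
as_contrast_matrix <- function(C, kind = "custom", check_rank = TRUE) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  rs <- rowSums(C)
  if (any(abs(rs) > 1e-10))
    stop("contrast row ", which(abs(rs) > 1e-10)[1L],
         " does not sum to zero", call. = FALSE)
  if (check_rank && (nrow(C) > ncol(C) || qr(C)$rank < nrow(C)))
    warning("contrast matrix does not have full row rank; ",
            "Wald/ANOVA tests use its row space, MCTPs test each row")
  if (is.null(rownames(C)))
    rownames(C) <- paste0("c", seq_len(nrow(C)))
  structure(C, class = c("contrast_matrix", "matrix"), kind = kind)
}

#' Read a contrast matrix from CSV (q rows, d columns, no header)
#' @param path path to the CSV file.
#' @return A `"contrast_matrix"`.
#' @export
read_contrast_csv <- function(path) {
  C <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(C) <- NULL
  as_contrast_matrix(C)
}
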