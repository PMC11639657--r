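# Shared fixtures: small random clustered designs and an independent
# Brunner-Munzel implementation used as an oracle for the two-sample,
# one-observation-per-cluster reduction.

toy_design <- function() {
  clustered_design(data.frame(group = c("1", "1", "2"),
                              cluster = c("1", "1", "1"),
                              value = c(1, 3, 4)))
}

# random design with ties (values on a small integer grid)
random_design <- function(d = NULL, n_max = 5, m_max = 4, vals = 1:6) {
  if (is.null(d)) d <- sample(2:4, 1)
  nv <- sample(2:n_max, d, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(d), function(i) {
    do.call(rbind, lapply(seq_len(nv[i]), function(j) {
      m <- sample(seq_len(m_max), 1)
      data.frame(group = i, cluster = j,
                 value = sample(vals, m, replace = TRUE))
    }))
  }))
  clustered_design(rows, group_order = as.character(seq_len(d)))
}

# two-sample design with one observation per cluster
two_sample_design <- function(x1, x2) {
  clustered_design(data.frame(
    group = rep(1:2, c(length(x1), length(x2))),
    cluster = c(seq_along(x1), seq_along(x2)),
    value = c(x1, x2)), group_order = c("1", "2"))
}

# textbook Brunner-Munzel statistic and Welch-type df (mid-ranks)
bm_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  r <- rank(c(x1, x2)); r1 <- rank(x1); r2 <- rank(x2)
  m1 <- mean(r[1:n1]); m2 <- mean(r[(n1 + 1):N])
  v1 <- sum((r[1:n1] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[(n1 + 1):N] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  list(stat = n1 * n2 * (m2 - m1) / (N * sqrt(n1 * v1 + n2 * v2)),
       df = (n1 * v1 + n2 * v2)^2 /
         ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1)),
       p_hat = (m2 - (n2 + 1) / 2) / n1)
}
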