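#' Distance-based multivariate permutation F-test
#'
#' Compares the multivariate feature distributions of two groups of burst
#' events with a non-parametric analogue of one-way ANOVA. With groups
#' \eqn{i = 1..K} (here K = 2) of sizes \eqn{n_i}, overall mean vector
#' \eqn{\bar Y} and group means \eqn{\bar Y_i}, the statistic is
#' \deqn{F = SS_A / SS_W,\quad
#'   SS_A = \sum_i n_i \|\bar Y - \bar Y_i\|^2 / (K - 1),\quad
#'   SS_W = \sum_i \sum_j \|\bar Y_i - Y_{ij}\|^2 / (N - K),}
#' with Euclidean distances. On one-dimensional data this reduces exactly
#' to the classical one-way ANOVA F. Significance comes from shuffling the
#' group labels over the pooled rows (group sizes fixed) `n_perm` times;
#' the p-value uses the add-one correction
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}, so it is
#' bounded below by \eqn{1/(n_{perm}+1)} and the test is exact-valid.
#'
#' Because the statistic is built on Euclidean distances it is sensitive
#' to feature scale; by default features are z-scored on the pooled data
#' first. Set `normalize = FALSE` to test in raw feature units.
#'
#' @param group_a,group_b numeric matrices (events x features) with equal
#'   column counts and at least 2 rows each.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @param normalize z-score features on the pooled data first (default
#'   TRUE).
#' @return object of class `perm_f`: list with `f_stat`, `p_value`,
#'   `n_perm`, `ss_a`, `ss_w`, `group_sizes`, `effect_size`
#'   (`ss_a / (ss_a + ss_w)`), `alpha`, `significant`.
#' @export
multivariate_perm_f <- function(group_a, group_b, n_perm = 10000, seed = 1,
                                normalize = TRUE) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B))
    stop_arg("groups have mismatched dimensionality (%d vs %d columns)",
             ncol(A), ncol(B))
  if (nrow(A) < 2 || nrow(B) < 2)
    stop_arg("each group needs at least 2 rows")
  nA <- nrow(A); nB <- nrow(B); N <- nA + nB; K <- 2
  Y <- rbind(A, B)
  if (normalize) {
    sds <- apply(Y, 2, stats::sd)
    if (any(sds == 0))
      stop_arg("degenerate statistic: constant feature(s) in the pooled data")
    Y <- scale(Y)
  }
  gmean <- colMeans(Y)
  ss_total <- sum(sweep(Y, 2, gmean)^2)
  ssa_raw_of <- function(idxA) {
    mA <- colMeans(Y[idxA, , drop = FALSE])
    mB <- (gmean * N - mA * nA) / nB
    nA * sum((gmean - mA)^2) + nB * sum((gmean - mB)^2)
  }
  ssa_raw <- ssa_raw_of(seq_len(nA))
  ssw_raw <- ss_total - ssa_raw
  if (ssw_raw <= 0)
    stop_arg("degenerate statistic: zero within-group sum of squares")
  ss_a <- ssa_raw / (K - 1)
  ss_w <- ssw_raw / (N - K)
  f_obs <- ss_a / ss_w
  set.seed(as.integer(seed))
  # F is monotone in the raw between-group SS (total SS is permutation
  # invariant), so permutations only need group-A column sums
  P <- matrix(0, n_perm, N)
  for (s in seq_len(n_perm)) P[s, sample.int(N, nA)] <- 1
  SA <- P %*% Y                      # n_perm x d group-A sums
  MA <- SA / nA
  MB <- sweep(-SA, 2, gmean * N, `+`) / nB
  ssa_perm <- nA * rowSums(sweep(MA, 2, gmean)^2) +
    nB * rowSums(sweep(MB, 2, gmean)^2)
  p <- (1 + sum(ssa_perm >= ssa_raw - 1e-12)) / (1 + n_perm)
  structure(list(f_stat = f_obs, p_value = p, n_perm = n_perm,
                 ss_a = ss_a, ss_w = ss_w, group_sizes = c(nA, nB),
                 effect_size = ss_a / (ss_a + ss_w),
                 alpha = 0.05, significant = p < 0.05),
            class = "perm_f")
}

#' @export
print.perm_f <- function(x, ...) {
  cat(sprintf("<perm_f> F = %.4f, p = %.4g (%d permutations), n = %d/%d\n",
              x$f_stat, x$p_value, x$n_perm, x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for `m` simultaneous tests.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop_arg("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Welch's two-sample t-test
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop_arg("each sample needs at least 2 values")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop_arg("degenerate test: both samples have zero variance")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' One-sample t-test
#'
#' @param sample numeric vector (n >= 2).
#' @param mu0 null mean (default 0).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
one_sample_t <- function(sample, mu0 = 0) {
  if (length(sample) < 2) stop_arg("sample needs at least 2 values")
  if (stats::var(sample) == 0) {
    if (mean(sample) == mu0) return(list(t = 0, df = length(sample) - 1, p = 1))
    stop_arg("degenerate test: zero-variance sample off the null mean")
  }
  tt <- stats::t.test(sample, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
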