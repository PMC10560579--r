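#' Fuzzy c-means clustering of burst embeddings
#'
#' Standard fuzzy c-means (fuzzifier `m = 2` by default) on the PCA scores,
#' run from `n_restarts` seeded initializations with the best objective
#' kept — c-means is initialization-sensitive, and restarts make the labels
#' stable. The fuzzy partition coefficient (FPC) is the mean squared
#' membership: 1 for a crisp partition, `1/k` for a maximally fuzzy one.
#'
#' @param scores events x dims numeric matrix (PCA embedding).
#' @param n_clusters number of clusters `k` (>= 1).
#' @param fuzzifier fuzziness exponent `m` (default 2).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed for the restarts.
#' @param iter_max maximum iterations per run (default 300).
#' @return object of class `fuzzy_clustering`: list with `memberships`
#'   (rows sum to 1), `centers`, `fpc`, `n_clusters`, `fuzzifier`,
#'   `objective`.
#' @export
fuzzy_cmeans <- function(scores, n_clusters, fuzzifier = 2, n_restarts = 10,
                         seed = 1, iter_max = 300) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0) stop_arg("empty input to fuzzy_cmeans")
  if (n_clusters < 1) stop_arg("n_clusters must be >= 1")
  if (n_clusters == 1) {
    u <- matrix(1, nrow(scores), 1)
    return(structure(list(memberships = u,
                          centers = matrix(colMeans(scores), 1),
                          fpc = 1, n_clusters = 1L, fuzzifier = fuzzifier,
                          objective = sum(scale(scores, scale = FALSE)^2)),
                     class = "fuzzy_clustering"))
  }
  if (n_clusters > nrow(scores))
    stop_arg("more clusters (%d) than points (%d)", n_clusters, nrow(scores))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(child_seed(seed, r))
    init <- scores[sample.int(nrow(scores), n_clusters), , drop = FALSE]
    init <- init + stats::rnorm(length(init), 0, 1e-6)  # break duplicate rows
    fit <- tryCatch(
      e1071::cmeans(scores, centers = init, iter.max = iter_max,
                    method = "cmeans", m = fuzzifier),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
  }
  if (is.null(best)) stop_arg("fuzzy c-means failed to converge from any restart")
  u <- best$membership
  structure(list(memberships = u, centers = best$centers,
                 fpc = mean(rowSums(u^2)), n_clusters = as.integer(n_clusters),
                 fuzzifier = fuzzifier, objective = best$withinerror),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("<fuzzy_clustering> k = %d, m = %g, FPC = %.3f, %d events\n",
              x$n_clusters, x$fuzzifier, x$fpc, nrow(x$memberships)))
  invisible(x)
}

#' Select the number of clusters by the fuzzy partition coefficient
#'
#' Runs [fuzzy_cmeans()] over a range of cluster numbers (excluding the
#' trivial `k = 1`, for which the FPC is identically 1) and returns the
#' `k` maximizing the FPC together with the full curve. A warning is
#' emitted when the curve is monotonically decreasing — the signature of a
#' single undifferentiated cloud, where the argmax (the smallest `k`) is
#' not evidence of real structure.
#'
#' @param scores events x dims matrix.
#' @param k_range integer vector of candidate cluster numbers (default 2:6;
#'   must exclude 1).
#' @param ... passed to [fuzzy_cmeans()].
#' @return list with `best_k`, `fpc` (named vector over `k_range`),
#'   `clusterings` (list of `fuzzy_clustering` objects).
#' @export
select_k_by_fpc <- function(scores, k_range = 2:6, ...) {
  if (any(k_range < 2)) stop_arg("k_range must exclude the trivial case k = 1")
  fits <- lapply(k_range, function(k) fuzzy_cmeans(scores, k, ...))
  fpc <- vapply(fits, `[[`, numeric(1), "fpc")
  names(fpc) <- k_range
  if (length(fpc) > 1 && all(diff(fpc) < 0) && max(fpc) < 0.75)
    warning("FPC decreases monotonically over k_range and never rises above 0.75; the data may form a single cluster")
  list(best_k = k_range[which.max(fpc)], fpc = fpc, clusterings = fits)
}

#' Assign SB/NGB/UC labels to a two-cluster solution
#'
#' Events whose maximum membership does not exceed `threshold` (0.6,
#' strictly) are labeled UC (unclassified) and excluded from class-specific
#' analyses. Of the two clusters, the one with the higher
#' membership-weighted mean relative beta-low gamma power is NGB — the
#' defining spectral signature of nested gamma events — and the other SB.
#' If the beta-low gamma means are tied within `tol`, mean duration breaks
#' the tie (NGB events are longer); if that is also tied the labeling is
#' refused and a manual override is required.
#'
#' @param clustering `fuzzy_clustering` with `n_clusters = 2`.
#' @param feats feature matrix with columns `rel_beta_low_gamma` and
#'   `duration` (same row order as the clustering input).
#' @param threshold UC membership threshold (default 0.6; an event at
#'   exactly 0.6 is UC).
#' @param tol tie tolerance for the cluster-identity rule (default 1e-8).
#' @return list with `labels` (character vector in SB/NGB/UC), `ngb_cluster`
#'   (index of the NGB cluster), `memberships`.
#' @export
assign_labels <- function(clustering, feats, threshold = 0.6, tol = 1e-8) {
  if (clustering$n_clusters != 2)
    stop_arg("label assignment requires exactly 2 clusters (got %d)",
             clustering$n_clusters)
  u <- clustering$memberships
  wmean <- function(col) colSums(u * feats[, col]) / colSums(u)
  beta <- wmean("rel_beta_low_gamma")
  if (abs(diff(beta)) > tol) {
    ngb <- unname(which.max(beta))
  } else {
    dur <- wmean("duration")
    if (abs(diff(dur)) <= tol)
      stop_arg(paste0("unresolved cluster identity: clusters are tied on both ",
                      "rel_beta_low_gamma and duration; supply labels manually"))
    ngb <- unname(which.max(dur))
  }
  hard <- apply(u, 1, which.max)
  labels <- ifelse(hard == ngb, "NGB", "SB")
  labels[apply(u, 1, max) <= threshold] <- "UC"
  list(labels = labels, ngb_cluster = ngb, memberships = u)
}
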