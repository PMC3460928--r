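#' NODF nestedness of a binary incidence matrix
#'
#' Nestedness by overlap and decreasing fill.  For every ordered pair of
#' rows (u, v) whose marginal totals satisfy MT_u > MT_v, the paired
#' nestedness is 100 times the number of shared presences divided by MT_v;
#' pairs with equal totals contribute 0 ("decreasing fill" is not
#' satisfied).  The same is computed over column pairs, and NODF is the
#' mean over all row pairs and column pairs, on a 0--100 scale.
#'
#' @param m a binary (or count, reduced to presence/absence) matrix, or a
#'   [bipartite_network]; at least 2 rows and 2 columns and no empty rows
#'   or columns.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(m) {
  if (inherits(m, "bipartite_network")) m <- m$weights
  b <- (as.matrix(m) > 0) * 1
  if (nrow(b) < 2 || ncol(b) < 2)
    stop("NODF needs at least 2 rows and 2 columns")
  if (any(rowSums(b) == 0) || any(colSums(b) == 0))
    stop("empty rows/columns: compact the matrix before scoring")
  (nodf_pair_sum(b) + nodf_pair_sum(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
}

## Sum of paired-nestedness terms over row pairs of a binary matrix.
nodf_pair_sum <- function(b) {
  tot <- rowSums(b)
  ov <- tcrossprod(b)                     # shared presences per row pair
  lo <- outer(tot, tot, pmin)
  keep <- upper.tri(ov) & outer(tot, tot, "!=")
  if (!any(keep)) return(0)
  sum(100 * ov[keep] / lo[keep])
}

#' Draw one CE null matrix
#'
#' The CE null model makes the probability of an interaction proportional
#' to the generalisation level of both partners: cell (i, j) is filled
#' independently with probability `(fill_row_i + fill_col_j) / 2`, where
#' the fills are the row/column marginal totals divided by the matrix
#' dimension.  Rows or columns that come out empty are compacted (dropped)
#' so the NODF estimator stays defined.
#'
#' @param m binary incidence matrix (counts are reduced to presences).
#' @param seed optional integer seed.
#' @return A binary matrix (possibly with fewer rows/columns than `m`).
#' @export
ce_null <- function(m, seed = NULL) {
  if (inherits(m, "bipartite_network")) m <- m$weights
  b <- (as.matrix(m) > 0) * 1
  with_seed(seed, {
    pr <- (outer(rowSums(b) / ncol(b), colSums(b) / nrow(b), "+")) / 2
    nm <- (matrix(runif(length(b)), nrow(b)) < pr) * 1
    nm[rowSums(nm) > 0, colSums(nm) > 0, drop = FALSE]
  })
}

#' Nestedness significance test against the CE null
#'
#' Computes the observed NODF and a Monte-Carlo null distribution of NODF
#' under the CE null model, with a one-sided p-value for nestedness
#' (null >= observed) using add-one smoothing so p is never exactly 0.
#' Null draws left with fewer than 2 rows or columns after compaction
#' score 0 (no scorable pairs).
#'
#' @param m binary incidence matrix or [bipartite_network].
#' @param replicates number of null matrices (default 1000).
#' @param seed integer seed.
#' @return Object of class `nestedness_test` with fields `nodf_observed`,
#'   `null_scores`, `p_value`, `replicates`.
#' @export
nestedness_test <- function(m, replicates = 1000, seed = 1) {
  if (inherits(m, "bipartite_network")) m <- m$weights
  if (replicates < 1) stop("replicates must be >= 1")
  obs <- nodf(m)
  null_scores <- with_seed(seed, vapply(seq_len(replicates), function(r) {
    nm <- ce_null(m)
    if (nrow(nm) < 2 || ncol(nm) < 2) 0 else nodf(nm)
  }, numeric(1)))
  structure(list(nodf_observed = obs, null_scores = null_scores,
                 p_value = (1 + sum(null_scores >= obs)) / (1 + replicates),
                 replicates = replicates),
            class = "nestedness_test")
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat("NODF nestedness test (CE null model)\n")
  cat(sprintf("  observed NODF = %.3f\n", x$nodf_observed))
  cat(sprintf("  null mean %.3f (sd %.3f), %d replicates\n",
              mean(x$null_scores), sd(x$null_scores), x$replicates))
  cat(sprintf("  one-sided p (null >= observed) = %.4g\n", x$p_value))
  invisible(x)
}
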