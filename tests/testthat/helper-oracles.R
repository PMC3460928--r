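# Fixtures and independent brute-force oracles used across the suite.

# Wrap a plain count matrix into a network, inventing ids/guilds as needed.
toy_net <- function(w, guild = "A", analysis_ready = TRUE) {
  if (is.null(rownames(w))) rownames(w) <- sprintf("h%02d", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- sprintf("s%02d", seq_len(ncol(w)))
  g <- if (length(guild) == 1) rep(guild, ncol(w)) else guild
  bipartite_network(w, stats::setNames(g, colnames(w)),
                    analysis_ready = analysis_ready)
}

# Two disjoint hollow-species pairs: the hand-evaluable modularity fixture.
two_pairs_net <- function() {
  w <- diag(1, 2)
  toy_net(w)
}

# NODF by literal enumeration of ordered row and column pairs.
nodf_oracle <- function(b) {
  b <- (b > 0) * 1
  pair_sum <- function(m) {
    tot <- rowSums(m)
    s <- 0
    for (u in seq_len(nrow(m)))
      for (v in seq_len(nrow(m)))
        if (tot[u] > tot[v])
          s <- s + 100 * sum(m[u, ] * m[v, ]) / tot[v]
    s
  }
  (pair_sum(b) + pair_sum(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
}

# All set partitions of n items as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (s in seq_len(k + 1)) rec(c(assign, s), max(k, s))
  }
  rec(integer(), 0)
  out
}

# Global modularity optimum by Bell-number enumeration.
best_modularity_exhaustive <- function(net) {
  n <- nrow(net$weights) + ncol(net$weights)
  best <- -Inf
  for (p in all_set_partitions(n))
    best <- max(best, modularity_score(net, p))
  best
}

# All non-negative integer matrices with the given marginal totals.
enumerate_tables <- function(r, cc) {
  nr <- length(r); nc <- length(cc)
  out <- list()
  fill_row <- function(i, mat, cleft) {
    if (i > nr) {
      if (all(cleft == 0)) out[[length(out) + 1]] <<- mat
      return(invisible())
    }
    cells <- function(j, row, left) {
      if (j == nc) {
        if (left <= cleft[nc]) {
          row[nc] <- left
          mat[i, ] <- row
          fill_row(i + 1, mat, cleft - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, cleft[j])) {
        row[j] <- v
        cells(j + 1, row, left - v)
      }
    }
    cells(1, numeric(nc), r[i])
    invisible()
  }
  fill_row(1, matrix(0, nr, nc), cc)
  out
}

# Exact min/max two-dimensional entropy over all tables with the margins.
entropy_extrema_oracle <- function(r, cc) {
  ent <- function(w) { p <- w[w > 0] / sum(w); -sum(p * log(p)) }
  hs <- vapply(enumerate_tables(r, cc), ent, numeric(1))
  c(min = min(hs), max = max(hs))
}

# Assortative robustness fixture: many redundant hub hollows shared by a
# couple of generalist species, plus a majority of specialist species each
# holding an exclusive low-degree hollow.  Directed removal spends its
# early removals on the (redundant) hubs while specialists persist on
# their private hollows, so the directed curve is gentler than random.
assortative_net <- function(n_hub = 15, n_core_s = 2, n_spec = 30) {
  nh <- n_hub + n_spec
  ns <- n_core_s + n_spec
  w <- matrix(0, nh, ns)
  w[seq_len(n_hub), seq_len(n_core_s)] <- 2             # redundant hubs
  for (k in seq_len(n_spec))
    w[n_hub + k, n_core_s + k] <- 1                     # private pairs
  toy_net(w)
}
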