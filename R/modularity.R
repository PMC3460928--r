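#' Build a partition object over the unipartite node set
#'
#' A partition assigns every node (hollows and species together) to a
#' module, and carries the modularity bookkeeping: total links L, and for
#' every module s the within-module link count l_s and the degree sum d_s.
#'
#' @param net a [bipartite_network].
#' @param membership integer vector of module ids, either of length
#'   `n_hollows + n_species` in unipartite order (hollows first, then
#'   species, both in matrix order), or named by node id.
#' @return Object of class `hollownet_partition`.
#' @export
make_partition <- function(net, membership) {
  uni <- as_unipartite(net)
  if (!is.null(names(membership)))
    membership <- membership[uni$labels]
  if (length(membership) != uni$n || anyNA(membership))
    stop("membership must assign every node exactly once")
  membership <- match(membership, unique(membership))  # relabel 1..k
  k <- max(membership)
  l_s <- numeric(k); d_s <- numeric(k)
  for (i in seq_len(uni$n)) {
    s <- membership[i]
    d_s[s] <- d_s[s] + uni$deg[i]
    l_s[s] <- l_s[s] + sum(membership[uni$adj[[i]]] == s)
  }
  l_s <- l_s / 2   # each within link seen from both ends
  structure(list(membership = structure(as.integer(membership),
                                        names = uni$labels),
                 level = uni$level, n_modules = k,
                 l_s = l_s, d_s = d_s, L = uni$L),
            class = "hollownet_partition")
}

#' @export
print.hollownet_partition <- function(x, ...) {
  cat(sprintf("Partition of %d nodes into %d modules (L = %d links)\n",
              length(x$membership), x$n_modules, x$L))
  print(table(module = x$membership))
  invisible(x)
}

#' Modularity of a partition
#'
#' M = sum over modules s of \[ l_s / L - (d_s / 2L)^2 \]: the within-module
#' link fraction minus the expectation under random assignment.  M is 0
#' when all nodes share one module, and near 0 for random assignments.
#'
#' @param net a [bipartite_network].
#' @param partition a `hollownet_partition` (from [make_partition] or
#'   [sa_optimize]) or a membership vector accepted by [make_partition].
#' @return Modularity M.
#' @export
modularity_score <- function(net, partition) {
  if (!inherits(partition, "hollownet_partition"))
    partition <- make_partition(net, partition)
  if (partition$L == 0) stop("network has no links")
  sum(partition$l_s / partition$L -
        (partition$d_s / (2 * partition$L))^2)
}

#' Simulated-annealing parameters
#'
#' The annealing schedule: at each temperature, `updates_per_T` single-node
#' reassignments plus `round(f * n_nodes)` collective split/merge moves are
#' proposed and accepted with the Metropolis probability
#' `min(1, exp(-dC / T))` for cost C = -M; then T is multiplied by the
#' cooling factor `c` until it falls below `t_final`.
#'
#' @param updates_per_T single-node moves per temperature (default 1000).
#' @param f iteration factor scaling the collective moves (default 0.1).
#' @param c cooling factor in (0, 1) (default 0.995).
#' @param t_initial initial temperature; `NULL` (default) auto-tunes from
#'   1/(2L) towards roughly 50% acceptance of initial proposals.
#' @param t_final final temperature; `NULL` (default) uses
#'   `1e-4 * t_initial`.
#' @param seed integer seed.
#' @return Object of class `sa_params`.
#' @export
sa_params <- function(updates_per_T = 1000, f = 0.1, c = 0.995,
                      t_initial = NULL, t_final = NULL, seed = 1) {
  if (updates_per_T < 1) stop("updates_per_T must be >= 1")
  if (c <= 0 || c >= 1) stop("cooling factor must be in (0, 1)")
  if (!is.null(t_initial) && !is.null(t_final) &&
      !(t_initial > t_final && t_final > 0))
    stop("need t_initial > t_final > 0")
  structure(list(updates_per_T = as.integer(updates_per_T), f = f, c = c,
                 t_initial = t_initial, t_final = t_final,
                 seed = as.integer(seed)),
            class = "sa_params")
}

#' Find a maximum-modularity partition by simulated annealing
#'
#' Optimises modularity on the unipartite view of the network (hollows and
#' species partitioned together) and returns the best partition ever
#' visited during the anneal.
#'
#' @param net a [bipartite_network].
#' @param params an [sa_params] object.
#' @return List with `partition` (a `hollownet_partition`) and `M`, its
#'   modularity.
#' @export
sa_optimize <- function(net, params = sa_params()) {
  uni <- as_unipartite(net)
  adj0 <- lapply(uni$adj, function(v) as.integer(v - 1L))
  res <- with_seed(params$seed,
                   sa_optimize_cpp(adj0, params$updates_per_T, params$f,
                                   params$c,
                                   if (is.null(params$t_initial)) -1
                                   else params$t_initial,
                                   if (is.null(params$t_final)) -1
                                   else params$t_final))
  part <- make_partition(net, res$membership)
  list(partition = part, M = modularity_score(net, part))
}

#' Modularity significance against degree-preserving null networks
#'
#' Generates `n_null` randomised networks by checkerboard swaps (preserving
#' every row and column degree of the binary incidence matrix), optimises
#' each with the same annealing budget, and reports the add-one-smoothed
#' p-value for the observed modularity.
#'
#' @param net a [bipartite_network].
#' @param n_null number of null networks (>= 19).
#' @param params an [sa_params]; null runs use seeds derived from
#'   `params$seed`.
#' @return List with `M_obs`, `p`, `M_null` (vector) and
#'   `rewiring_warning` (TRUE when a null failed to reach 10 x L swaps).
#' @export
modularity_significance <- function(net, n_null = 199,
                                    params = sa_params()) {
  if (n_null < 19) stop("n_null must be >= 19")
  obs <- sa_optimize(net, params)
  b <- (net$weights > 0) * 1L
  L <- sum(b)
  warn <- FALSE
  M_null <- vapply(seq_len(n_null), function(r) {
    sd <- stage_seed(params$seed, paste0("null", r))
    rw <- with_seed(sd, rewire_checkerboard_cpp(b, 10L * L, 1000L * L))
    if (rw$swaps < 10L * L) warn <<- TRUE
    nm <- rw$matrix
    dimnames(nm) <- dimnames(b)
    nnet <- bipartite_network(nm, net$guilds)
    np <- params; np$seed <- stage_seed(sd, "sa")
    sa_optimize(nnet, np)$M
  }, numeric(1))
  list(M_obs = obs$M, p = (1 + sum(M_null >= obs$M)) / (1 + n_null),
       M_null = M_null, partition = obs$partition,
       rewiring_warning = warn)
}

#' Multi-run consensus of annealed partitions
#'
#' Runs the annealer `n_runs` times from distinct seeds, tabulates how
#' often each module count occurs (as percentages of runs), selects the
#' "minimum partition with largest optimisation of modularity" -- among
#' runs whose M is within 1% of the best, the one with fewest modules
#' (ties: higher M, then lower run index) -- and scores the cohesion of
#' each selected module.
#'
#' Cohesion of a module is the mean over runs of the fraction of its node
#' pairs co-assigned to one module in that run (singleton modules score 1).
#' An all-or-nothing variant (fraction of runs in which *all* the module's
#' nodes are co-assigned) is also returned.
#'
#' @param net a [bipartite_network].
#' @param n_runs number of annealing runs (default 25).
#' @param params an [sa_params]; run r uses seed `params$seed + r - 1`.
#' @return Object of class `consensus_result` with fields `runs` (data
#'   frame of run, M, n_modules), `module_count_distribution`,
#'   `selected` (partition), `selected_M`, `cohesion`,
#'   `cohesion_all_or_nothing` and `memberships` (matrix, runs x nodes).
#' @export
consensus_runs <- function(net, n_runs = 25, params = sa_params()) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    pr <- params; pr$seed <- params$seed + r - 1L
    runs[[r]] <- sa_optimize(net, pr)
  }
  M <- vapply(runs, `[[`, numeric(1), "M")
  k <- vapply(runs, function(x) x$partition$n_modules, integer(1))
  dist <- table(k) / n_runs * 100
  near <- which(M >= max(M) * (1 - 0.01 * sign(max(M))) - 1e-12)
  ## fewest modules among near-optimal runs; ties -> higher M -> lower run
  sel <- near[order(k[near], -M[near], near)][1]
  selected <- runs[[sel]]$partition
  memb <- do.call(rbind, lapply(runs, function(x) x$partition$membership))
  coh <- cohesion_scores(selected, memb)
  structure(list(runs = data.frame(run = seq_len(n_runs), M = M,
                                   n_modules = k),
                 module_count_distribution = dist,
                 selected = selected, selected_M = M[sel],
                 selected_run = sel,
                 cohesion = coh$pairwise,
                 cohesion_all_or_nothing = coh$all_or_nothing,
                 memberships = memb),
            class = "consensus_result")
}

cohesion_scores <- function(selected, memberships) {
  mods <- sort(unique(selected$membership))
  pairwise <- all_or_nothing <- setNames(numeric(length(mods)),
                                         paste0("module", mods))
  for (mi in seq_along(mods)) {
    nodes <- names(selected$membership)[selected$membership == mods[mi]]
    if (length(nodes) < 2) {
      pairwise[mi] <- 1; all_or_nothing[mi] <- 1
      next
    }
    per_run <- apply(memberships[, nodes, drop = FALSE], 1, function(m) {
      tab <- table(m)
      same <- sum(choose(tab, 2)) / choose(length(nodes), 2)
      c(same, as.numeric(length(tab) == 1))
    })
    pairwise[mi] <- mean(per_run[1, ])
    all_or_nothing[mi] <- mean(per_run[2, ])
  }
  list(pairwise = pairwise, all_or_nothing = all_or_nothing)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d annealing runs\n", nrow(x$runs)))
  cat("  module-count distribution (% of runs):\n")
  print(round(x$module_count_distribution, 1))
  cat(sprintf("  selected: run %d, %d modules, M = %.4f\n",
              x$selected_run, x$selected$n_modules, x$selected_M))
  cat("  module cohesion (pairwise co-assignment):\n")
  print(round(x$cohesion, 3))
  invisible(x)
}

#' Normalised mutual information between two labelings
#'
#' NMI = 2 I(a; b) / (H(a) + H(b)); 1 for identical partitions (up to
#' relabeling), 0 for independent ones.  Used to score planted-partition
#' recovery.
#'
#' @param a,b vectors of labels of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  ex <- outer(pa, pb)
  pos <- joint > 0
  i <- sum(joint[pos] * log(joint[pos] / ex[pos]))
  2 * i / (ha + hb)
}
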