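#' Mean links per species
#'
#' Total number of links (positive cells) divided by the total number of
#' nodes, species plus hollows.  The divisor counts *all* nodes: this is
#' the convention under which the printed panel values are internally
#' consistent (links-per-species times node count recovers the link total
#' that connectance implies).
#'
#' @param net a [bipartite_network].
#' @return Links per species node.
#' @export
links_per_species <- function(net) {
  b <- net$weights > 0
  sum(b) / (nrow(b) + ncol(b))
}

#' Connectance
#'
#' Realised links divided by possible links (rows x columns of the
#' incidence matrix).
#'
#' @param net a [bipartite_network].
#' @return Connectance in (0, 1\].
#' @export
connectance <- function(net) {
  b <- net$weights > 0
  sum(b) / length(b)
}

#' Species strength (sum of dependencies)
#'
#' The dependency of hollow h on species s is the fraction of h's
#' individuals contributed by s; the strength of species s is the sum of
#' these dependencies over hollows.  Strengths sum to the number of
#' hollows (each hollow's dependencies sum to 1).
#'
#' @param net a [bipartite_network].
#' @param transpose if `TRUE`, compute hollow strengths from species
#'   dependencies instead.
#' @return Named numeric vector of strengths.
#' @export
species_strength <- function(net, transpose = FALSE) {
  w <- net$weights
  if (transpose) w <- t(w)
  rs <- rowSums(w)
  if (any(rs == 0)) stop("row(s) with zero total")
  colSums(w / rs)
}

## base-2 Shannon entropy of a positive weight vector
shannon2 <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log2(p))
}

#' Quantitative (weighted) linkage density
#'
#' Mean effective number of partners per node, weighted by node marginal
#' totals: LD = 1/2 \[ sum_h (A_h/m) 2^(H_h) + sum_s (A_s/m) 2^(H_s) \],
#' where A are marginal totals, m the grand total and H the base-2
#' Shannon entropy of a node's interaction weights, so 2^H is its
#' effective partner number.  Unlike the binary links-per-species, this
#' accounts for how evenly interactions are used.
#'
#' @param net a [bipartite_network].
#' @return Linkage density.
#' @export
linkage_density <- function(net) {
  w <- net$weights
  m <- sum(w)
  hr <- apply(w, 1, shannon2)
  hc <- apply(w, 2, shannon2)
  (sum(rowSums(w) / m * 2^hr) + sum(colSums(w) / m * 2^hc)) / 2
}

## Greedy minimum-entropy allocation under fixed marginals: repeatedly
## put as much mass as possible on the (largest-row, largest-column) cell.
h2_min_alloc <- function(r, cc) {
  alloc <- matrix(0, length(r), length(cc))
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(cc)
    a <- min(r[i], cc[j])
    alloc[i, j] <- alloc[i, j] + a
    r[i] <- r[i] - a; cc[j] <- cc[j] - a
  }
  alloc
}

## Maximum-entropy integer allocation under fixed marginals: floor of the
## independence expectation, then distribute the remaining units one at a
## time to the feasible cell with the largest residual.
h2_max_alloc <- function(r, cc) {
  m <- sum(r)
  e <- outer(r, cc) / m
  alloc <- floor(e)
  rdef <- r - rowSums(alloc)
  cdef <- cc - colSums(alloc)
  resid <- e - alloc
  while (sum(rdef) > 0) {
    feas <- outer(rdef > 0, cdef > 0, "&")
    cand <- which(feas)
    pick <- cand[which.max(resid[cand])]
    alloc[pick] <- alloc[pick] + 1
    resid[pick] <- resid[pick] - 1
    i <- (pick - 1) %% length(r) + 1
    j <- (pick - 1) %/% length(r) + 1
    rdef[i] <- rdef[i] - 1; cdef[j] <- cdef[j] - 1
  }
  alloc
}

## natural-log two-dimensional entropy of a count matrix
entropy2d <- function(w) {
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

#' H2' network specialisation
#'
#' Standardised two-dimensional interaction entropy:
#' H2' = (H2max - H2) / (H2max - H2min), where H2 is the Shannon entropy
#' of the interaction probabilities p_ij = a_ij / m, and H2max / H2min are
#' the largest and smallest entropies attainable by integer matrices with
#' the observed marginal totals (H2max by proportional allocation with
#' integer repair, H2min by greedy diagonal packing).  0 means the
#' interactions are as unspecific as the marginals allow; 1 means complete
#' specialisation.
#'
#' @param net a [bipartite_network] (>= 2 rows and columns, positive
#'   counts).
#' @return H2' in \[0, 1\]; when the marginals admit only one allocation
#'   (H2max = H2min) returns 0 with attribute `degenerate = TRUE`.
#' @export
h2_prime <- function(net) {
  w <- net$weights
  if (nrow(w) < 2 || ncol(w) < 2)
    stop("H2' needs at least 2 rows and 2 columns")
  r <- rowSums(w); cc <- colSums(w)
  h2 <- entropy2d(w)
  h2max <- entropy2d(h2_max_alloc(r, cc))
  h2min <- entropy2d(h2_min_alloc(r, cc))
  if (h2max - h2min < 1e-12)
    return(structure(0, degenerate = TRUE))
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

#' Variance ratio of the higher trophic level
#'
#' V = Var(per-hollow totals) / sum over species of Var(that species'
#' counts across hollows), with population variances.  Equals 1 in
#' expectation when species are distributed independently; values above 1
#' indicate positive aggregation (species covary), below 1 compensation.
#'
#' @param net a [bipartite_network] with >= 2 hollows.
#' @param presence if `TRUE`, use presence/absence instead of abundances.
#' @return The variance ratio (> 0).
#' @export
v_ratio <- function(net, presence = FALSE) {
  w <- net$weights
  if (presence) w <- (w > 0) * 1
  if (nrow(w) < 2) stop("variance ratio needs >= 2 hollows")
  pvar <- function(x) mean(x^2) - mean(x)^2
  denom <- sum(apply(w, 2, pvar))
  if (denom == 0) stop("all species constant across hollows")
  pvar(rowSums(w)) / denom
}

#' Assemble the full metric panel for one network
#'
#' One row of the panel reported for each (sub-)network: node counts,
#' NODF, component count, links per species, connectance, linkage
#' density, H2', variance ratio, and (optionally) the robustness columns
#' PE, RPE, SE, RSE.
#'
#' @param net a [bipartite_network].
#' @param nestedness_replicates CE null replicates for the NODF test
#'   (0 skips the test and reports the raw NODF only).
#' @param robustness_replicates extinction replicates (0 skips).
#' @param seed integer seed for the Monte-Carlo stages.
#' @return Object of class `network_report` (a one-row data frame with
#'   columns SP, TH, NODF, NODF_p, M, L_S, C, LD, H2, V_ratio, PE, RPE,
#'   SE, RSE).
#' @export
full_report <- function(net, nestedness_replicates = 1000,
                        robustness_replicates = 100, seed = 1) {
  b <- net$weights > 0
  nodf_p <- NA_real_
  if (nestedness_replicates > 0) {
    nt <- nestedness_test(net, replicates = nestedness_replicates,
                          seed = stage_seed(seed, "nestedness"))
    nodf_val <- nt$nodf_observed; nodf_p <- nt$p_value
  } else nodf_val <- nodf(net)
  rob <- c(PE = NA_real_, RPE = NA_real_, SE = NA_real_, RSE = NA_real_)
  if (robustness_replicates > 0) {
    rs <- robustness_experiment(net, replicates = robustness_replicates,
                                seed = stage_seed(seed, "robustness"))
    rob <- c(PE = rs$PE, RPE = rs$RPE, SE = rs$SE, RSE = rs$RSE)
  }
  out <- data.frame(SP = ncol(b), TH = nrow(b), NODF = nodf_val,
                    NODF_p = nodf_p, M = connected_components(net)$count,
                    L_S = links_per_species(net), C = connectance(net),
                    LD = linkage_density(net), H2 = as.numeric(h2_prime(net)),
                    V_ratio = v_ratio(net), PE = rob[["PE"]],
                    RPE = rob[["RPE"]], SE = rob[["SE"]],
                    RSE = rob[["RSE"]])
  class(out) <- c("network_report", "data.frame")
  out
}
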