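#' Specification for a planted-modular synthetic network
#'
#' @param n_hollows,n_species matrix dimensions.
#' @param n_modules number of planted blocks (>= 1, at most
#'   `min(n_hollows, n_species)`).
#' @param p_in,p_out within- and between-block link probabilities;
#'   `p_in >= p_out` so the planted structure is real.
#' @param count_mean mean of the positive counts (counts are drawn as
#'   1 + geometric, so every link has weight >= 1 and the weight
#'   distribution is heavy-tailed, echoing the dominance of a few abundant
#'   generalists in real emergence data).
#' @param guild_proportions named numeric vector over guild codes summing
#'   to 1.
#' @param seed integer seed.
#' @return An object of class `modular_spec`.
#' @export
modular_spec <- function(n_hollows, n_species, n_modules = 4,
                         p_in = 0.5, p_out = 0.02, count_mean = 3,
                         guild_proportions = c(A = 0.3, B = 0.25, C = 0.15,
                                               D = 0.15, E = 0.15),
                         seed = 1) {
  if (n_modules < 1 || n_modules > min(n_hollows, n_species))
    stop("n_modules must be in 1..min(n_hollows, n_species)")
  if (p_in < p_out) stop("p_in must be >= p_out for planted structure")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("link probabilities must lie in [0, 1]")
  if (abs(sum(guild_proportions) - 1) > 1e-8)
    stop("guild_proportions must sum to 1")
  if (!all(names(guild_proportions) %in% names(guild_codes)))
    stop("unknown guild code in guild_proportions")
  structure(list(n_hollows = n_hollows, n_species = n_species,
                 n_modules = n_modules, p_in = p_in, p_out = p_out,
                 count_mean = count_mean,
                 guild_proportions = guild_proportions, seed = seed),
            class = "modular_spec")
}

## counts drawn as 1 + geometric with mean count_mean (>= 1)
rcounts <- function(n, count_mean) {
  if (count_mean <= 1) return(rep(1, n))
  1 + rgeom(n, prob = 1 / count_mean)
}

## Split n items as evenly as possible into k consecutive blocks.
block_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  sizes
}

## Allocate `n` items to categories by largest-remainder rounding.
allocate_counts <- function(n, proportions) {
  raw <- proportions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

assign_guilds <- function(species, proportions) {
  counts <- allocate_counts(length(species), proportions)
  structure(rep(names(proportions), counts), names = species)
}

#' Generate a planted-modular bipartite network
#'
#' Hollows and species are split as evenly as possible into
#' `spec$n_modules` blocks; each within-block cell becomes a link with
#' probability `p_in` and each between-block cell with probability `p_out`;
#' links get 1 + geometric counts.  Nodes left isolated are repaired with a
#' single within-block link (rather than dropped) so the planted partition
#' stays intact for recovery experiments and the output is analysis-ready.
#'
#' @param spec a [modular_spec].
#' @return List with `net` (a [bipartite_network]) and `planted`, the
#'   true block membership as a data frame (`node_id`, `level`, `module`).
#' @export
generate_modular <- function(spec) {
  stopifnot(inherits(spec, "modular_spec"))
  with_seed(spec$seed, {
    nh <- spec$n_hollows; ns <- spec$n_species; k <- spec$n_modules
    hb <- rep(seq_len(k), block_sizes(nh, k))
    sb <- rep(seq_len(k), block_sizes(ns, k))
    hid <- sprintf("H%03d", seq_len(nh))
    sid <- sprintf("S%03d", seq_len(ns))
    same <- outer(hb, sb, "==")
    p <- ifelse(same, spec$p_in, spec$p_out)
    link <- matrix(runif(nh * ns) < p, nh, ns)
    ## repair isolated nodes with one within-block link
    for (i in which(rowSums(link) == 0)) {
      cand <- which(sb == hb[i])
      link[i, cand[sample.int(length(cand), 1)]] <- TRUE
    }
    for (j in which(colSums(link) == 0)) {
      cand <- which(hb == sb[j])
      link[cand[sample.int(length(cand), 1)], j] <- TRUE
    }
    w <- matrix(0, nh, ns, dimnames = list(hid, sid))
    w[link] <- rcounts(sum(link), spec$count_mean)
    guilds <- assign_guilds(sid, spec$guild_proportions)
    net <- bipartite_network(w, guilds)
    planted <- data.frame(node_id = c(hid, sid),
                          level = rep(c("hollow", "species"), c(nh, ns)),
                          module = c(hb, sb), stringsAsFactors = FALSE)
    list(net = net, planted = planted)
  })
}

#' Generate a perfectly nested ("staircase") binary network
#'
#' Upper-left triangular incidence matrix: row i carries ones in columns
#' 1..L_i with L_i decreasing from `n_species` to 1, so marginal totals
#' decrease and every pair of rows (and of columns) is fully nested; its
#' NODF is 100 whenever no two marginal totals tie (guaranteed for square
#' matrices and whenever `n_species >= n_hollows`).
#'
#' @param n_hollows,n_species dimensions (both >= 2).
#' @return A [bipartite_network] with unit weights (all species guild "A").
#' @export
generate_nested <- function(n_hollows, n_species) {
  if (n_hollows < 2 || n_species < 2) stop("dimensions must be >= 2")
  lens <- round(n_species - (seq_len(n_hollows) - 1) *
                  (n_species - 1) / (n_hollows - 1))
  lens <- pmax(1, pmin(n_species, lens))
  w <- matrix(0, n_hollows, n_species,
              dimnames = list(sprintf("H%03d", seq_len(n_hollows)),
                              sprintf("S%03d", seq_len(n_species))))
  for (i in seq_len(n_hollows)) w[i, seq_len(lens[i])] <- 1
  bipartite_network(w, structure(rep("A", n_species), names = colnames(w)))
}

#' Generate a community with independent species abundances
#'
#' Each species' abundances across sites are independent Poisson draws with
#' a species-specific mean scattered (lognormally) around
#' `mean_abundance`; no covariance between species is induced, so the
#' expected variance ratio ([v_ratio]) is 1.
#'
#' @param n_species,n_sites dimensions (both >= 2); sites play the role of
#'   hollows.
#' @param mean_abundance positive; centre of the species mean distribution.
#' @param seed integer seed.
#' @return A [bipartite_network] (not necessarily analysis-ready: zero
#'   rows/columns can occur at low abundance and are retained, since the
#'   variance ratio is defined on the raw abundance table).
#' @export
generate_independent <- function(n_species, n_sites, mean_abundance = 5,
                                 seed = 1) {
  if (n_species < 2 || n_sites < 2) stop("dimensions must be >= 2")
  with_seed(seed, {
    lam <- mean_abundance * exp(rnorm(n_species, 0, 0.3))
    w <- matrix(rpois(n_sites * n_species, rep(lam, each = n_sites)),
                n_sites, n_species,
                dimnames = list(sprintf("T%03d", seq_len(n_sites)),
                                sprintf("S%03d", seq_len(n_species))))
    bipartite_network(w, structure(rep("A", n_species),
                                   names = colnames(w)),
                      analysis_ready = FALSE)
  })
}

#' Generate a survey-scale demonstration network
#'
#' An 87-hollow by 157-species sparse count network emulating the
#' statistical structure of a full tree-hollow emergence survey:
#' connectance near 0.09, heavy-tailed species degrees (at least 40% of
#' species with 1--3 links), five planted interaction blocks, and guild
#' sizes proportional to a realistic survey (xylophagous 21, saprophagous
#' 45, xylomycetophagous 38, predators 26, commensals 28, scaled to 157
#' species).  This is a synthetic stand-in for unpublished field data; it
#' reproduces marginal structure only, not any real community.
#'
#' @param seed integer seed.
#' @return A [bipartite_network].
#' @export
generate_paper_scale <- function(seed = 1) {
  nh <- 87L; ns <- 157L; k <- 5L
  with_seed(seed, {
    hb <- rep(seq_len(k), block_sizes(nh, k))
    sb <- rep(seq_len(k), block_sizes(ns, k))
    hid <- sprintf("H%03d", seq_len(nh))
    sid <- sprintf("S%03d", seq_len(ns))
    ## heavy-tailed expected species degrees, rescaled so the expected
    ## link total pins connectance near 0.09
    target_mean <- 0.09 * nh
    d <- exp(rnorm(ns, 0, 1.4))
    d <- d * (target_mean * ns) / sum(d)
    deg <- pmax(1L, pmin(nh, rpois(ns, d)))
    ## hollow attractiveness: larger hollows attract more species
    attract <- exp(rnorm(nh, 0, 0.6))
    link <- matrix(FALSE, nh, ns)
    for (j in seq_len(ns)) {
      wgt <- attract * ifelse(hb == sb[j], 5, 1)
      rows <- sample.int(nh, deg[j], prob = wgt)
      link[rows, j] <- TRUE
    }
    for (i in which(rowSums(link) == 0)) {
      cand <- which(sb == hb[i])
      link[i, cand[sample.int(length(cand), 1)]] <- TRUE
    }
    w <- matrix(0, nh, ns, dimnames = list(hid, sid))
    w[link] <- rcounts(sum(link), 3)
    props <- c(C = 21, A = 45, B = 38, E = 26, D = 28) / 158
    guilds <- assign_guilds(sid, props[order(names(props))])
    bipartite_network(w, guilds)
  })
}
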