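#' @useDynLib hollownet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize rbinom rgeom rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv tail write.csv write.table
NULL

#' Trophic guild codes
#'
#' Single-letter codes used throughout for the five saproxylic feeding
#' guilds: A saprophagous, B xylomycetophagous, C xylophagous, D commensal,
#' E predator.  Guilds A--C use woody resources directly ("wood-dependent");
#' D and E depend on the presence or activity of other saproxylic insects
#' ("insect-dependent").
#'
#' @format Named character vector mapping code to guild name.
#' @export
guild_codes <- c(A = "saprophagous", B = "xylomycetophagous",
                 C = "xylophagous", D = "commensal", E = "predator")

#' Construct a bipartite hollow-by-species network
#'
#' The universal container for all analyses: a weighted incidence matrix
#' whose rows are tree-hollow microhabitats (lower trophic level) and whose
#' columns are insect species (higher trophic level), with counts of emerged
#' individuals as weights, plus a guild annotation for every species.
#'
#' @param weights numeric matrix of non-negative integer counts with row
#'   names (hollow ids) and column names (species ids).
#' @param guilds named character vector mapping every species id to one of
#'   the codes in [guild_codes].
#' @param forest_type optional named character vector mapping hollow ids to
#'   a forest-type label.
#' @param analysis_ready logical; if `TRUE` (default) require every row and
#'   column to have at least one positive entry.
#' @return An object of class `bipartite_network`: a list with elements
#'   `weights`, `guilds` and `forest_type`.
#' @export
bipartite_network <- function(weights, guilds, forest_type = NULL,
                              analysis_ready = TRUE) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("weights must have hollow ids as row names and species ids as column names")
  if (anyDuplicated(rownames(weights)))
    stop("duplicate hollow ids")
  if (anyDuplicated(colnames(weights)))
    stop("duplicate species ids")
  if (any(weights < 0) || any(weights != round(weights)))
    stop("weights must be non-negative integer counts")
  storage.mode(weights) <- "double"
  sp <- colnames(weights)
  missing_guild <- setdiff(sp, names(guilds))
  if (length(missing_guild))
    stop("species without guild annotation: ",
         paste(missing_guild, collapse = ", "))
  guilds <- guilds[sp]
  bad <- !guilds %in% names(guild_codes)
  if (any(bad))
    stop("unknown guild code(s): ", paste(unique(guilds[bad]), collapse = ", "),
         " for species ", paste(sp[bad], collapse = ", "))
  if (analysis_ready) {
    if (any(rowSums(weights) == 0))
      stop("hollow row(s) with no interactions: ",
           paste(rownames(weights)[rowSums(weights) == 0], collapse = ", "))
    if (any(colSums(weights) == 0))
      stop("species column(s) with no interactions: ",
           paste(colnames(weights)[colSums(weights) == 0], collapse = ", "))
  }
  structure(list(weights = weights, guilds = guilds,
                 forest_type = forest_type),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  w <- x$weights
  cat("Bipartite hollow-species network\n")
  cat(sprintf("  %d tree hollows x %d insect species, %d links, %d individuals\n",
              nrow(w), ncol(w), sum(w > 0), sum(w)))
  cat("  guilds:", paste(sprintf("%s=%d", names(table(x$guilds)),
                                 as.integer(table(x$guilds))), collapse = " "),
      "\n")
  invisible(x)
}

hollow_ids <- function(net) rownames(net$weights)
species_ids <- function(net) colnames(net$weights)

#' Read a network from edge-list and guild files
#'
#' @param edge_list_path CSV with header `hollow_id,species_id,count`; counts
#'   are positive integers and duplicate (hollow, species) rows are summed.
#' @param guild_path CSV with header `species_id,guild`, guild a code in
#'   [guild_codes].
#' @return A [bipartite_network] with rows and columns in lexicographic
#'   order of their ids.
#' @export
read_network <- function(edge_list_path, guild_path) {
  edges <- read.csv(edge_list_path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  if (nrow(edges) == 0) stop("no interactions in ", edge_list_path)
  names(edges) <- c("hollow_id", "species_id", "count")
  bad <- which(edges$count <= 0 | edges$count != round(edges$count) |
                 !is.finite(edges$count))
  if (length(bad))
    stop("non-integer or non-positive count at line ", bad[1] + 1L,
         " of ", edge_list_path)
  gl <- read.csv(guild_path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character"))
  names(gl) <- c("species_id", "guild")
  guilds <- structure(gl$guild, names = gl$species_id)
  missing_guild <- setdiff(unique(edges$species_id), names(guilds))
  if (length(missing_guild))
    stop("species missing from guild file: ",
         paste(sort(missing_guild), collapse = ", "))
  hs <- sort(unique(edges$hollow_id))
  ss <- sort(unique(edges$species_id))
  w <- matrix(0, length(hs), length(ss), dimnames = list(hs, ss))
  for (k in seq_len(nrow(edges)))
    w[edges$hollow_id[k], edges$species_id[k]] <-
      w[edges$hollow_id[k], edges$species_id[k]] + edges$count[k]
  bipartite_network(w, guilds)
}

#' Write a network as edge-list and guild CSV files
#'
#' Inverse of [read_network]: `read_network(write_network(net, ...))`
#' reproduces the weight matrix exactly.
#'
#' @param net a [bipartite_network].
#' @param edge_list_path,guild_path output paths.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, edge_list_path, guild_path) {
  w <- net$weights
  idx <- which(w > 0, arr.ind = TRUE)
  edges <- data.frame(hollow_id = rownames(w)[idx[, 1]],
                      species_id = colnames(w)[idx[, 2]],
                      count = w[idx])
  edges <- edges[order(edges$hollow_id, edges$species_id), ]
  write.csv(edges, edge_list_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(species_id = names(net$guilds), guild = net$guilds),
            guild_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Export the incidence matrix as TSV
#'
#' Hollows as rows, a header row of species ids.
#'
#' @param net a [bipartite_network].
#' @param path output path.
#' @export
export_matrix <- function(net, path) {
  write.table(net$weights, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(net)
}

#' Guild-based sub-network filters
#'
#' @param mode one of `"complete"` (all guilds), `"direct"` (wood-dependent,
#'   guilds A, B, C), `"indirect"` (insect-dependent, guilds D, E) or
#'   `"single-guild"`.
#' @param guild_set for `mode = "single-guild"`, the single guild code.
#' @return An object of class `guild_filter`.
#' @export
guild_filter <- function(mode = c("complete", "direct", "indirect",
                                  "single-guild"),
                         guild_set = NULL) {
  mode <- match.arg(mode)
  gs <- switch(mode,
               complete = names(guild_codes),
               direct = c("A", "B", "C"),
               indirect = c("D", "E"),
               `single-guild` = guild_set)
  if (length(gs) == 0) stop("guild_set must be non-empty")
  if (mode == "single-guild" && length(gs) != 1)
    stop("single-guild filter needs exactly one guild code")
  if (!all(gs %in% names(guild_codes)))
    stop("unknown guild code(s): ",
         paste(setdiff(gs, names(guild_codes)), collapse = ", "))
  structure(list(mode = mode, guild_set = gs), class = "guild_filter")
}

#' Extract a guild-defined sub-network
#'
#' Keeps the species whose guild belongs to the filter's guild set, then
#' drops hollow rows left with no interactions.  Dropping empty hollows
#' after filtering is what makes the number of participating tree hollows
#' vary between sub-networks (e.g. predators occupying only a subset of all
#' surveyed hollows).
#'
#' @param net a [bipartite_network].
#' @param filter a [guild_filter], one of the mode keywords, or a character
#'   vector of guild codes.
#' @return A [bipartite_network] restricted to the selected guilds.
#' @export
extract_subnetwork <- function(net, filter) {
  if (is.character(filter)) {
    filter <- if (length(filter) == 1 &&
                  filter %in% c("complete", "direct", "indirect"))
      guild_filter(filter)
    else if (length(filter) == 1 && filter %in% names(guild_codes))
      guild_filter("single-guild", filter)
    else
      structure(list(mode = "custom", guild_set = filter),
                class = "guild_filter")
  }
  if (!all(filter$guild_set %in% names(guild_codes)))
    stop("unknown guild code(s) in filter")
  keep <- names(net$guilds)[net$guilds %in% filter$guild_set]
  if (length(keep) == 0)
    stop("empty sub-network: no species in guild set ",
         paste(filter$guild_set, collapse = ","))
  w <- net$weights[, keep, drop = FALSE]
  w <- w[rowSums(w) > 0, , drop = FALSE]
  if (nrow(w) == 0) stop("empty sub-network: no occupied hollows remain")
  ft <- net$forest_type
  if (!is.null(ft)) ft <- ft[intersect(names(ft), rownames(w))]
  bipartite_network(w, net$guilds[keep], forest_type = ft)
}

## Unipartite view used by modularity / cartography: hollows first
## (indices 1..nh), then species (nh+1..nh+ns); edges are positive cells.
as_unipartite <- function(net) {
  b <- net$weights > 0
  nh <- nrow(b); ns <- ncol(b)
  adj <- vector("list", nh + ns)
  for (i in seq_len(nh)) adj[[i]] <- nh + which(b[i, ])
  for (j in seq_len(ns)) adj[[nh + j]] <- which(b[, j])
  list(n = nh + ns, nh = nh, ns = ns, adj = adj,
       deg = lengths(adj), L = sum(b),
       labels = c(rownames(b), colnames(b)),
       level = rep(c("hollow", "species"), c(nh, ns)))
}

#' Connected components of the bipartite graph
#'
#' Components of the unipartite graph whose vertices are hollows and
#' species and whose edges are positive cells.  Isolated components
#' (typically small sets of interacting pairs detached from the main web)
#' are what the Table-1-style report counts in its `M` column.
#'
#' @param net a [bipartite_network].
#' @return List with `count` and `assignment`, a data frame with columns
#'   `node_id`, `level`, `component`.
#' @export
connected_components <- function(net) {
  g <- igraph::graph_from_biadjacency_matrix(net$weights > 0)
  cmp <- igraph::components(g)
  uni <- as_unipartite(net)
  ## igraph orders vertices rows-then-columns, matching as_unipartite
  list(count = cmp$no,
       assignment = data.frame(node_id = uni$labels, level = uni$level,
                               component = as.integer(cmp$membership),
                               stringsAsFactors = FALSE))
}

#' Node degrees and link count
#'
#' A link is any cell with a positive count; degree is the number of links
#' incident to a node.
#'
#' @param net a [bipartite_network].
#' @return List with `species_degree` and `hollow_degree` (named integer
#'   vectors) and `total_links`.
#' @export
node_degrees <- function(net) {
  b <- net$weights > 0
  list(species_degree = colSums(b), hollow_degree = rowSums(b),
       total_links = sum(b))
}

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.  All stochastic operations funnel through
## this so there is no hidden global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic sub-seed for a named pipeline stage (kept below 2^31).
stage_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}
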