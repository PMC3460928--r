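#' Within-module degree z-score
#'
#' For node i in module s_i with k_i links to other nodes of s_i,
#' z_i = (k_i - mean_s k) / sd_s k, standardised over the nodes of s_i
#' using the population standard deviation.  Modules whose nodes all have
#' the same within-module degree (sd 0) assign z = 0 to every member:
#' there is no within-module differentiation to measure.  Hubs are nodes
#' with z >= 2.5.
#'
#' @param net a [bipartite_network].
#' @param partition a `hollownet_partition` or membership vector.
#' @return Named numeric vector of z-scores over all nodes.
#' @export
within_module_degree <- function(net, partition) {
  if (!inherits(partition, "hollownet_partition"))
    partition <- make_partition(net, partition)
  uni <- as_unipartite(net)
  mem <- partition$membership[uni$labels]
  kin <- vapply(seq_len(uni$n),
                function(i) sum(mem[uni$adj[[i]]] == mem[i]), numeric(1))
  z <- numeric(uni$n)
  for (s in unique(mem)) {
    idx <- which(mem == s)
    mu <- mean(kin[idx])
    sdv <- sqrt(mean((kin[idx] - mu)^2))   # population sd
    z[idx] <- if (sdv > 0) (kin[idx] - mu) / sdv else 0
  }
  structure(z, names = uni$labels)
}

#' Participation coefficient
#'
#' P_i = 1 - sum over modules s of (k_is / k_i)^2, where k_is is the
#' number of links of node i into module s and k_i its total degree.
#' P is 0 when all links stay inside the node's own module and approaches
#' 1 as links spread uniformly over many modules.
#'
#' @inheritParams within_module_degree
#' @return Named numeric vector of P in \[0, 1).
#' @export
participation_coefficient <- function(net, partition) {
  if (!inherits(partition, "hollownet_partition"))
    partition <- make_partition(net, partition)
  uni <- as_unipartite(net)
  mem <- partition$membership[uni$labels]
  p <- vapply(seq_len(uni$n), function(i) {
    ki <- uni$deg[i]
    if (ki == 0) stop("isolated node: ", uni$labels[i])
    kis <- table(mem[uni$adj[[i]]])
    1 - sum((kis / ki)^2)
  }, numeric(1))
  structure(p, names = uni$labels)
}

## role threshold table: non-hub (z < 2.5) P cuts and hub (z >= 2.5) P cuts;
## each upper bound is inclusive.
role_thresholds <- list(
  nonhub = c(R1 = 0.05, R2 = 0.62, R3 = 0.80, R4 = 1.00),
  hub    = c(R5 = 0.30, R6 = 0.75, R7 = 1.00),
  z_hub  = 2.5
)

#' Classify nodes into universal roles R1-R7
#'
#' From the (z, P) plane: non-hubs (z < 2.5) are R1 ultra-peripheral
#' (P <= 0.05), R2 peripheral (P <= 0.62), R3 non-hub connector
#' (P <= 0.80) or R4 non-hub kinless; hubs (z >= 2.5) are R5 provincial
#' hub (P <= 0.30), R6 connector hub (P <= 0.75) or R7 kinless hub.
#' The thresholds partition the plane totally and unambiguously.
#'
#' @param z,P numeric vectors (equal length, finite) of within-module
#'   degree z-scores and participation coefficients.
#' @param thresholds threshold table; defaults to [role_thresholds].
#' @return Character vector of roles (`"R1"` .. `"R7"`), named as `z`.
#' @export
classify_roles <- function(z, P, thresholds = role_thresholds) {
  stopifnot(length(z) == length(P), all(is.finite(z)), all(is.finite(P)))
  out <- character(length(z))
  for (i in seq_along(z)) {
    cuts <- if (z[i] >= thresholds$z_hub) thresholds$hub else
      thresholds$nonhub
    out[i] <- names(cuts)[which(P[i] <= cuts + 1e-12)[1]]
  }
  structure(out, names = names(z))
}

#' Role counts and percentages
#'
#' @param roles character vector of roles from [classify_roles].
#' @return Data frame with `role`, `count`, `percentage` (summing to 100)
#'   over all seven roles.
#' @export
role_summary <- function(roles) {
  lev <- paste0("R", 1:7)
  tab <- table(factor(roles, levels = lev))
  data.frame(role = lev, count = as.integer(tab),
             percentage = as.numeric(tab) / length(roles) * 100,
             stringsAsFactors = FALSE)
}

#' Full node cartography for a partitioned network
#'
#' Combines degree, within-module degree z, participation coefficient P
#' and role for every node (the data behind a z-P role diagram).
#'
#' @inheritParams within_module_degree
#' @return Data frame with columns `node_id`, `level`, `module`, `k`,
#'   `z`, `P`, `role`.
#' @export
node_cartography <- function(net, partition) {
  if (!inherits(partition, "hollownet_partition"))
    partition <- make_partition(net, partition)
  uni <- as_unipartite(net)
  z <- within_module_degree(net, partition)
  P <- participation_coefficient(net, partition)
  data.frame(node_id = uni$labels, level = uni$level,
             module = as.integer(partition$membership[uni$labels]),
             k = as.integer(uni$deg), z = as.numeric(z),
             P = as.numeric(P),
             role = as.character(classify_roles(z, P)),
             stringsAsFactors = FALSE)
}
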