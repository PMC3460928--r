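#' Pipeline configuration
#'
#' Defaults follow the full study protocol: 1000 CE null replicates for
#' nestedness, 25 annealing runs for the consensus, 100 extinction
#' replicates, and 199 degree-preserving nulls for modularity
#' significance.
#'
#' @param edge_list_path,guild_path input CSVs (see [read_network]); omit
#'   both and pass `net` to [run_all] to analyse an in-memory network.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stage derives its own sub-seed from it
#'   by stable hashing of the stage name, so adding a stage never perturbs
#'   another stage's random stream.
#' @param nestedness_replicates,consensus_runs,robustness_replicates,n_null
#'   Monte-Carlo sizes per stage.
#' @param sa an [sa_params] object for all annealing stages.
#' @param skip character vector of stages to skip: any of
#'   `"nestedness"`, `"modularity"`, `"significance"`, `"cartography"`,
#'   `"robustness"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(edge_list_path = NULL, guild_path = NULL,
                       out_dir = "hollownet-out", seed = 1,
                       nestedness_replicates = 1000, consensus_runs = 25,
                       robustness_replicates = 100, n_null = 199,
                       sa = sa_params(), skip = character()) {
  bad <- setdiff(skip, c("nestedness", "modularity", "significance",
                         "cartography", "robustness"))
  if (length(bad)) stop("unknown stage(s) in skip: ",
                        paste(bad, collapse = ", "))
  structure(list(edge_list_path = edge_list_path, guild_path = guild_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 nestedness_replicates = nestedness_replicates,
                 consensus_runs = consensus_runs,
                 robustness_replicates = robustness_replicates,
                 n_null = n_null, sa = sa, skip = skip),
            class = "run_config")
}

## the eight analysis networks: complete, the two interaction types, and
## the five guilds (skipping guilds absent from the input)
build_networks <- function(net) {
  nets <- list(complete = net)
  for (f in c("direct", "indirect"))
    nets[[f]] <- tryCatch(extract_subnetwork(net, f), error = function(e) NULL)
  for (g in names(guild_codes))
    nets[[guild_codes[[g]]]] <-
      tryCatch(extract_subnetwork(net, g), error = function(e) NULL)
  Filter(Negate(is.null), nets)
}

#' Run the full analysis pipeline
#'
#' Reads (or receives) the hollow-by-species network, builds the complete
#' network plus the interaction-type and guild sub-networks, and runs
#' every stage on each: NODF nestedness with CE null test, component
#' count, the quantitative metric panel, annealed modularity with
#' multi-run consensus (and optional significance against
#' degree-preserving nulls), node cartography on the selected partition,
#' and extinction robustness.  Writes `table1.tsv` (one metric row per
#' network), `table2.tsv` (module-count distribution per network),
#' `cartography.csv`, `robustness_curves.csv`, `modularity.json` and
#' `manifest.json` to the output directory.  Deterministic given the
#' seed; any stage error aborts with the stage name and removes partial
#' outputs.
#'
#' @param config a [run_config].
#' @param net optionally, a [bipartite_network] to analyse instead of
#'   reading from the configured paths.
#' @return Invisibly, a list with all per-network results and the output
#'   file paths.
#' @export
run_all <- function(config = run_config(), net = NULL) {
  if (is.null(net)) {
    if (is.null(config$edge_list_path))
      stop("stage input: no network and no edge_list_path configured")
    net <- read_network(config$edge_list_path, config$guild_path)
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  outfiles <- file.path(config$out_dir,
                        c("table1.tsv", "table2.tsv", "cartography.csv",
                          "robustness_curves.csv", "modularity.json",
                          "manifest.json"))
  names(outfiles) <- basename(outfiles)
  on_fail <- function(stage, e) {
    unlink(outfiles)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  nets <- build_networks(net)
  results <- list()
  t1 <- t2 <- cart <- curves <- list()
  mod_json <- list()
  for (nm in names(nets)) {
    sub <- nets[[nm]]
    sseed <- stage_seed(config$seed, nm)
    row <- tryCatch(
      full_report(sub,
                  nestedness_replicates =
                    if ("nestedness" %in% config$skip) 0
                    else config$nestedness_replicates,
                  robustness_replicates =
                    if ("robustness" %in% config$skip) 0
                    else config$robustness_replicates,
                  seed = sseed),
      error = function(e) on_fail(paste0("metrics:", nm), e))
    res <- list(report = row)
    if (!"modularity" %in% config$skip) {
      sa <- config$sa; sa$seed <- stage_seed(sseed, "consensus")
      cons <- tryCatch(consensus_runs(sub, config$consensus_runs, sa),
                       error = function(e) on_fail(paste0("modularity:", nm), e))
      res$consensus <- cons
      t2[[nm]] <- cons$module_count_distribution
      mod_json[[nm]] <- list(M = cons$selected_M,
                             n_modules = cons$selected$n_modules,
                             cohesion = as.list(round(cons$cohesion, 4)))
      if (!"significance" %in% config$skip) {
        sa2 <- config$sa; sa2$seed <- stage_seed(sseed, "significance")
        sig <- tryCatch(
          modularity_significance(sub, config$n_null, sa2),
          error = function(e) on_fail(paste0("significance:", nm), e))
        res$significance <- sig
        mod_json[[nm]]$M_significance_p <- sig$p
        mod_json[[nm]]$rewiring_warning <- sig$rewiring_warning
      }
      if (!"cartography" %in% config$skip) {
        cg <- tryCatch(node_cartography(sub, cons$selected),
                       error = function(e) on_fail(paste0("cartography:", nm), e))
        cg <- cbind(network = nm, cg)
        res$cartography <- cg
        cart[[nm]] <- cg
      }
    }
    if (!"robustness" %in% config$skip) {
      for (ord in c("random", "degree")) {
        cv <- extinction_sequence(sub, ord,
                                  seed = stage_seed(sseed, paste0("curve-", ord)))
        curves[[paste(nm, ord)]] <-
          data.frame(network = nm, order = ord, step = seq_len(nrow(cv)) - 1,
                     x = cv$x, y = cv$y)
      }
    }
    t1[[nm]] <- cbind(network = nm, row)
    results[[nm]] <- res
  }
  table1 <- do.call(rbind, t1)
  rownames(table1) <- NULL
  write.table(format(table1, digits = 8, trim = TRUE, scientific = FALSE),
              outfiles["table1.tsv"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- sort(unique(unlist(lapply(t2, function(d) as.integer(names(d))))))
  t2m <- do.call(rbind, lapply(names(t2), function(nm) {
    p <- setNames(numeric(length(counts)), counts)
    p[names(t2[[nm]])] <- as.numeric(t2[[nm]])
    data.frame(network = nm, t(p), check.names = FALSE)
  }))
  if (!is.null(t2m))
    write.table(t2m, outfiles["table2.tsv"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (length(cart))
    write.csv(do.call(rbind, c(cart, make.row.names = FALSE)),
              outfiles["cartography.csv"], row.names = FALSE, quote = FALSE)
  if (length(curves))
    write.csv(do.call(rbind, c(curves, make.row.names = FALSE)),
              outfiles["robustness_curves.csv"], row.names = FALSE,
              quote = FALSE)
  if (length(mod_json))
    jsonlite::write_json(mod_json, outfiles["modularity.json"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    seed = config$seed,
    networks = names(nets),
    settings = list(nestedness_replicates = config$nestedness_replicates,
                    consensus_runs = config$consensus_runs,
                    robustness_replicates = config$robustness_replicates,
                    n_null = config$n_null,
                    sa = unclass(config$sa), skip = config$skip),
    versions = list(hollownet = as.character(utils::packageVersion("hollownet")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, outfiles["manifest.json"],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, table1 = table1,
                 files = outfiles[file.exists(outfiles)]))
}

#' Validate pipeline inputs
#'
#' Reports, without failing: species lacking a guild annotation, unknown
#' guild codes, duplicate edges (which [read_network] will sum), and
#' non-positive or non-integer counts.
#'
#' @param edge_list_path,guild_path input CSVs as for [read_network].
#' @return Data frame with columns `severity` (`"error"` or `"note"`),
#'   `issue` and `detail`; zero rows when the inputs are clean.
#' @export
validate_inputs <- function(edge_list_path, guild_path) {
  issues <- list()
  push <- function(sev, issue, detail)
    issues[[length(issues) + 1]] <<-
      data.frame(severity = sev, issue = issue, detail = detail)
  edges <- read.csv(edge_list_path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  names(edges) <- c("hollow_id", "species_id", "count")
  gl <- read.csv(guild_path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character"))
  names(gl) <- c("species_id", "guild")
  if (nrow(edges) == 0) push("error", "empty edge list", edge_list_path)
  bad <- which(edges$count <= 0 | edges$count != round(edges$count))
  for (k in bad)
    push("error", "invalid count",
         sprintf("line %d: %s,%s,%s", k + 1L, edges$hollow_id[k],
                 edges$species_id[k], format(edges$count[k])))
  miss <- setdiff(unique(edges$species_id), gl$species_id)
  for (s in miss) push("error", "species without guild", s)
  unk <- unique(gl$guild[!gl$guild %in% names(guild_codes)])
  for (g in unk) push("error", "unknown guild code", g)
  dup <- duplicated(edges[c("hollow_id", "species_id")])
  for (k in which(dup))
    push("note", "duplicate edge (will be summed)",
         paste(edges$hollow_id[k], edges$species_id[k]))
  if (length(issues) == 0)
    return(data.frame(severity = character(), issue = character(),
                      detail = character()))
  do.call(rbind, issues)
}
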