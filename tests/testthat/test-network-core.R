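test_that("edge-list assembly sums duplicates and orders ids lexicographically", {
  ed <- tempfile(fileext = ".csv"); gd <- tempfile(fileext = ".csv")
  writeLines(c("hollow_id,species_id,count",
               "h2,sB,3", "h1,sA,1", "h1,sA,4", "h2,sA,2"), ed)
  writeLines(c("species_id,guild", "sA,A", "sB,C"), gd)
  net <- read_network(ed, gd)
  expect_equal(rownames(net$weights), c("h1", "h2"))
  expect_equal(colnames(net$weights), c("sA", "sB"))
  expect_equal(net$weights["h1", "sA"], 5)  # duplicates summed
  expect_equal(net$weights["h2", "sB"], 3)
  expect_equal(unname(net$guilds["sB"]), "C")
})

test_that("reader rejects empty files, missing guilds and bad counts", {
  ed <- tempfile(fileext = ".csv"); gd <- tempfile(fileext = ".csv")
  writeLines("hollow_id,species_id,count", ed)
  writeLines(c("species_id,guild", "sA,A"), gd)
  expect_error(read_network(ed, gd), "no interactions")
  writeLines(c("hollow_id,species_id,count", "h1,sZ,2"), ed)
  expect_error(read_network(ed, gd), "sZ")
  writeLines(c("hollow_id,species_id,count", "h1,sA,2", "h2,sA,-1"), ed)
  expect_error(read_network(ed, gd), "line 3")
  writeLines(c("hollow_id,species_id,count", "h1,sA,2.5"), ed)
  expect_error(read_network(ed, gd), "line 2")
})

test_that("write/read round-trip preserves the matrix exactly", {
  gm <- generate_modular(modular_spec(12, 9, n_modules = 3, seed = 11))
  ed <- tempfile(fileext = ".csv"); gd <- tempfile(fileext = ".csv")
  write_network(gm$net, ed, gd)
  back <- read_network(ed, gd)
  expect_identical(back$weights, gm$net$weights)
  expect_identical(back$guilds, gm$net$guilds)
})

test_that("guild filtering keeps selected species and drops emptied hollows", {
  w <- matrix(0, 4, 5)
  w[1, 1:2] <- 1; w[2, 3] <- 2; w[3, 4] <- 1; w[4, 5] <- 3
  net <- toy_net(w, guild = c("C", "C", "A", "D", "E"))
  sub <- extract_subnetwork(net, "C")
  expect_equal(colnames(sub$weights), c("s01", "s02"))
  expect_equal(nrow(sub$weights), 1)  # only hollow 1 uses guild C
  direct <- extract_subnetwork(net, "direct")
  expect_equal(ncol(direct$weights), 3)
  expect_equal(nrow(direct$weights), 2)
  expect_error(extract_subnetwork(extract_subnetwork(net, "A"), "B"),
               "empty sub-network")
})

test_that("the complete filter is the identity on analysis-ready networks", {
  gm <- generate_modular(modular_spec(15, 12, n_modules = 3, seed = 2))
  sub <- extract_subnetwork(gm$net, "complete")
  expect_identical(sub$weights, gm$net$weights)
})

test_that("retained hollow count matches a brute-force count of non-empty rows", {
  gm <- generate_modular(modular_spec(40, 30, n_modules = 4, p_in = 0.25,
                                      p_out = 0.01, seed = 7))
  keep <- names(gm$net$guilds)[gm$net$guilds %in% c("D", "E")]
  expected_rows <- sum(rowSums(gm$net$weights[, keep, drop = FALSE] > 0) > 0)
  sub <- extract_subnetwork(gm$net, "indirect")
  expect_equal(nrow(sub$weights), expected_rows)
})

test_that("component counting matches the planted structure", {
  expect_equal(connected_components(two_pairs_net())$count, 2)
  full <- toy_net(matrix(1, 3, 4))
  expect_equal(connected_components(full)$count, 1)
  # main block plus two isolated interacting pairs
  w <- matrix(0, 5, 6)
  w[1:3, 1:4] <- 1; w[4, 5] <- 2; w[5, 6] <- 1
  expect_equal(connected_components(toy_net(w))$count, 3)
  # invariant under row/column permutation
  wp <- w[sample(5), sample(6)]
  expect_equal(connected_components(toy_net(wp))$count, 3)
})

test_that("degrees count positive cells and balance the link total", {
  full <- toy_net(matrix(1:12, 3, 4))
  d <- node_degrees(full)
  expect_true(all(d$species_degree == 3) && all(d$hollow_degree == 4))
  expect_equal(d$total_links, 12)
  dd <- node_degrees(toy_net(diag(2, 3)))
  expect_true(all(dd$species_degree == 1) && dd$total_links == 3)
  gm <- generate_modular(modular_spec(25, 18, n_modules = 3, seed = 4))
  d <- node_degrees(gm$net)
  brute <- sum(gm$net$weights > 0)
  expect_equal(sum(d$species_degree), brute)
  expect_equal(sum(d$hollow_degree), brute)
  expect_equal(d$total_links, brute)
})

test_that("constructor enforces the data-model invariants", {
  w <- matrix(1, 2, 2, dimnames = list(c("h1", "h2"), c("s1", "s2")))
  expect_error(bipartite_network(w, c(s1 = "A")), "s2")
  expect_error(bipartite_network(w, c(s1 = "A", s2 = "Q")), "guild")
  w2 <- w; w2[, 2] <- 0
  expect_error(bipartite_network(w2, c(s1 = "A", s2 = "A")),
               "no interactions")
  w3 <- w; w3[1, 1] <- -1
  expect_error(bipartite_network(w3, c(s1 = "A", s2 = "A")),
               "non-negative")
})
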