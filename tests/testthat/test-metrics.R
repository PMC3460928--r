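test_that("links per species divides links by the total node count", {
  expect_equal(links_per_species(toy_net(diag(1, 5))), 0.5)
  expect_equal(links_per_species(toy_net(matrix(1, 3, 4))), 12 / 7)
  # printed-panel consistency: 21 species, 80 hollows, 264 links
  expect_equal(round(264 / (21 + 80), 3), 2.614)
})

test_that("connectance is links over cells", {
  expect_equal(connectance(toy_net(matrix(2, 4, 6))), 1)
  gm <- generate_modular(modular_spec(12, 9, n_modules = 3, seed = 13))
  b <- gm$net$weights > 0
  expect_equal(connectance(gm$net), sum(b) / (12 * 9))
  expect_equal(connectance(gm$net) * 12 * 9, sum(b))
})

test_that("species strengths are dependencies that sum to the hollow count", {
  # one species alone in every hollow: strength = number of hollows
  w <- matrix(c(5, 3, 2), 3, 1)
  w <- cbind(w, 0); w[1, 2] <- 1  # second species needed for validity
  net <- toy_net(w)
  s <- species_strength(net)
  expect_equal(sum(s), 3)
  # two species with equal counts everywhere: each gets half of each hollow
  eq <- toy_net(matrix(4, 5, 2))
  expect_equal(unname(species_strength(eq)), c(2.5, 2.5))
  # conservation on a random fixture
  gm <- generate_modular(modular_spec(18, 14, n_modules = 2, seed = 19))
  expect_equal(sum(species_strength(gm$net)), 18, tolerance = 1e-9)
  expect_equal(sum(species_strength(gm$net, transpose = TRUE)), 14,
               tolerance = 1e-9)
})

test_that("linkage density equals effective partner numbers", {
  expect_equal(linkage_density(toy_net(matrix(3, 4, 4))), 4)  # uniform k x k
  expect_equal(linkage_density(toy_net(diag(7, 5))), 1)       # one-to-one
  # skewed 2x2: hand-computed entropy evaluation
  w <- rbind(c(3, 1), c(0, 4))
  m <- 8
  h_rows <- c(-(3 / 4 * log2(3 / 4) + 1 / 4 * log2(1 / 4)), 0)
  h_cols <- c(0, -(1 / 5 * log2(1 / 5) + 4 / 5 * log2(4 / 5)))
  expected <- (sum(c(4, 4) / m * 2^h_rows) + sum(c(3, 5) / m * 2^h_cols)) / 2
  expect_equal(linkage_density(toy_net(w)), expected)
})

test_that("H2' spans its range: diagonal = 1, independence ~ 0", {
  dn <- toy_net(diag(10, 6))
  expect_equal(as.numeric(h2_prime(dn)), 1)
  # matrix equal to the outer product of its marginals
  r <- c(20, 10, 10); cc <- c(16, 12, 8, 4)
  ind <- outer(r, cc) / 40
  expect_true(all(ind == round(ind)))
  expect_lt(as.numeric(h2_prime(toy_net(ind))), 0.05)
  # transposition invariance
  gm <- generate_modular(modular_spec(10, 8, n_modules = 2, seed = 23))
  expect_equal(as.numeric(h2_prime(gm$net)),
               as.numeric(h2_prime(toy_net(t(gm$net$weights)))),
               tolerance = 1e-9)
})

test_that("H2 extrema heuristics track the exhaustive-allocation oracle", {
  margins <- list(
    list(r = c(4, 3, 2), cc = c(3, 3, 3)),
    list(r = c(6, 2, 2), cc = c(5, 3, 2)),
    list(r = c(5, 4, 3), cc = c(6, 4, 2)),
    list(r = c(2, 2, 2), cc = c(3, 2, 1)))
  for (mg in margins) {
    oracle <- entropy_extrema_oracle(mg$r, mg$cc)
    hmin <- hollownet:::entropy2d(hollownet:::h2_min_alloc(mg$r, mg$cc))
    hmax <- hollownet:::entropy2d(hollownet:::h2_max_alloc(mg$r, mg$cc))
    expect_lt(abs(hmin - oracle["min"]), 0.05)
    expect_lt(abs(hmax - oracle["max"]), 0.05)
  }
})

test_that("variance ratio detects aggregation and compensation", {
  # single species: numerator equals denominator
  one <- toy_net(cbind(c(3, 1, 4), c(1, 1, 1)))  # s2 constant: var 0
  expect_equal(v_ratio(one), 1)
  # two identical species double the ratio
  x <- c(4, 1, 3, 7)
  dup <- toy_net(matrix(c(x, x), 4, 2))
  expect_equal(v_ratio(dup), 2)
  # checkerboard compensation pushes below 1
  comp <- toy_net(rbind(c(5, 1), c(1, 5), c(5, 1), c(1, 5)))
  expect_lt(v_ratio(comp), 1)
  expect_error(v_ratio(toy_net(matrix(2, 3, 2))), "constant")
})

test_that("the full report row is internally consistent", {
  gm <- generate_modular(modular_spec(20, 15, n_modules = 3, seed = 29))
  rep1 <- full_report(gm$net, nestedness_replicates = 50,
                      robustness_replicates = 10, seed = 5)
  b <- gm$net$weights > 0
  expect_equal(rep1$SP, 15)
  expect_equal(rep1$TH, 20)
  expect_equal(rep1$L_S * (rep1$SP + rep1$TH), sum(b), tolerance = 1e-9)
  expect_equal(rep1$C * rep1$SP * rep1$TH, sum(b), tolerance = 1e-9)
  expect_true(rep1$H2 >= 0 && rep1$H2 <= 1)
  expect_true(rep1$RPE >= 0 && rep1$RPE <= 1)
  expect_gt(rep1$V_ratio, 0)
  # skipping robustness leaves those columns empty
  rep2 <- full_report(gm$net, nestedness_replicates = 0,
                      robustness_replicates = 0)
  expect_true(all(is.na(c(rep2$PE, rep2$RPE, rep2$SE, rep2$RSE, rep2$NODF_p))))
})

test_that("wood-dependent style density asymmetry shows up in the panel", {
  # build a network where direct guilds are dense and indirect sparse
  set.seed(41)
  wd <- matrix(rbinom(30 * 12, 1, 0.45) * (1 + rgeom(360, 0.5)), 30, 12)
  id <- matrix(rbinom(30 * 10, 1, 0.08) * (1 + rgeom(300, 0.5)), 30, 10)
  w <- cbind(wd, id)
  keep <- rowSums(w) > 0
  w <- w[keep, colSums(w) > 0, drop = FALSE]
  guild <- c(rep("A", 12), rep("E", 10))[colSums(cbind(wd, id)[keep, ]) > 0]
  net <- toy_net(w, guild = guild)
  direct <- extract_subnetwork(net, "direct")
  indirect <- extract_subnetwork(net, "indirect")
  expect_gt(connectance(direct), connectance(indirect))
  expect_gt(linkage_density(direct), linkage_density(indirect))
})
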