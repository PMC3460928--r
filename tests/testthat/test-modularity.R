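test_that("modularity identities hold exactly", {
  gm <- generate_modular(modular_spec(12, 10, n_modules = 3, seed = 6))
  n <- 22
  # single module: L/L - (2L/2L)^2 = 0 on any network
  expect_identical(modularity_score(gm$net, rep(1, n)), 0)
  # two disjoint pairs split into their pairs: 2 x (1/2 - (2/4)^2) = 0.5
  expect_equal(modularity_score(two_pairs_net(), c(1, 2, 1, 2)), 0.5)
  # relabelling invariance
  part <- c(rep(1, 11), rep(2, 11))
  expect_equal(modularity_score(gm$net, part),
               modularity_score(gm$net, 3 - part))
  expect_error(modularity_score(gm$net, rep(1, 5)), "every node")
})

test_that("random assignments average to zero modularity", {
  # the random-assignment expectation carries a finite-size bias of order
  # sum(deg^2)/(4 L^2), so a moderately sized network is needed
  gm <- generate_modular(modular_spec(40, 32, n_modules = 4, p_in = 0.5,
                                      p_out = 0.05, seed = 2))
  set.seed(123)
  ms <- replicate(200, modularity_score(gm$net, sample(1:4, 72, TRUE)))
  expect_lt(abs(mean(ms)), 0.02)
})

test_that("partition bookkeeping satisfies its invariants", {
  gm <- generate_modular(modular_spec(10, 8, n_modules = 2, seed = 3))
  part <- make_partition(gm$net, gm$planted$module)
  expect_equal(part$L, sum(gm$net$weights > 0))
  expect_lte(sum(part$l_s), part$L)
  expect_equal(sum(part$d_s), 2 * part$L)  # degree sums always total 2L
  # with no between-module links, within links account for everything
  iso <- generate_modular(modular_spec(10, 8, n_modules = 2, p_out = 0,
                                       seed = 3))
  piso <- make_partition(iso$net, iso$planted$module)
  expect_equal(sum(piso$l_s), piso$L)
})

test_that("annealing attains the exhaustive optimum on tiny networks", {
  nets <- list(
    two_pairs_net(),                                   # 4 nodes
    toy_net(rbind(c(1, 1, 0), c(1, 0, 1))),            # path-like, 5 nodes
    toy_net(rbind(c(2, 1, 0, 0), c(1, 3, 0, 0),
                  c(0, 0, 1, 2), c(0, 0, 2, 1))))      # 2 blocks, 8 nodes
  for (net in nets) {
    best <- best_modularity_exhaustive(net)
    for (s in 1:3) {
      fit <- sa_optimize(net, sa_params(seed = s))
      expect_equal(fit$M, best, tolerance = 1e-9)
    }
  }
})

test_that("reported M matches an independent rescoring of the partition", {
  gm <- generate_modular(modular_spec(20, 15, n_modules = 3, seed = 8))
  fit <- sa_optimize(gm$net, sa_params(seed = 4))
  expect_equal(fit$M, modularity_score(gm$net, fit$partition$membership))
  g <- igraph::graph_from_biadjacency_matrix(gm$net$weights > 0)
  ref <- igraph::modularity(g, fit$partition$membership)
  expect_equal(fit$M, ref, tolerance = 1e-9)
})

test_that("planted partitions are recovered and recovery degrades with mixing", {
  gm <- generate_modular(modular_spec(40, 30, n_modules = 4, p_in = 0.5,
                                      p_out = 0.02, seed = 10))
  fit <- sa_optimize(gm$net, sa_params(seed = 1))
  expect_gte(nmi(fit$partition$membership, gm$planted$module), 0.9)
  blur <- generate_modular(modular_spec(40, 30, n_modules = 4, p_in = 0.3,
                                        p_out = 0.3, seed = 10))
  fit2 <- sa_optimize(blur$net, sa_params(seed = 1))
  expect_lt(nmi(fit2$partition$membership, blur$planted$module),
            nmi(fit$partition$membership, gm$planted$module))
})

test_that("SA is deterministic given its seed", {
  gm <- generate_modular(modular_spec(15, 12, n_modules = 3, seed = 5))
  a <- sa_optimize(gm$net, sa_params(seed = 7))
  b <- sa_optimize(gm$net, sa_params(seed = 7))
  expect_identical(a$partition$membership, b$partition$membership)
  expect_identical(a$M, b$M)
})

test_that("modularity significance separates planted structure from nulls", {
  gm <- generate_modular(modular_spec(25, 18, n_modules = 4, p_in = 0.5,
                                      p_out = 0.02, seed = 12))
  sig <- modularity_significance(gm$net, n_null = 19, sa_params(seed = 2))
  expect_lte(sig$p, 0.05)
  expect_equal(length(sig$M_null), 19)
  expect_error(modularity_significance(gm$net, n_null = 5), "n_null")
})

test_that("degree-preserving rewiring keeps both degree sequences", {
  gm <- generate_modular(modular_spec(15, 12, n_modules = 3, seed = 9))
  b <- (gm$net$weights > 0) * 1L
  rw <- with(list(), {
    set.seed(3)
    hollownet:::rewire_checkerboard_cpp(b, 10L * sum(b), 1000L * sum(b))
  })
  expect_equal(rowSums(rw$matrix), rowSums(b))
  expect_equal(colSums(rw$matrix), colSums(b))
  expect_gte(rw$swaps, 10L * sum(b))
})

test_that("consensus on disconnected blocks is concentrated and fully cohesive", {
  # blocks dense enough to be internally connected, so the components
  # and the annealed modules both equal the planted count
  gm <- generate_modular(modular_spec(20, 16, n_modules = 4, p_in = 0.8,
                                      p_out = 0, seed = 3))
  expect_equal(connected_components(gm$net)$count, 4)
  cons <- consensus_runs(gm$net, n_runs = 6, sa_params(seed = 5))
  expect_equal(sum(cons$module_count_distribution), 100)
  expect_equal(names(which.max(cons$module_count_distribution)), "4")
  expect_true(all(cons$cohesion >= 0.99))
  expect_equal(cons$selected$n_modules, 4)
})

test_that("the selected consensus partition is near-optimal with fewest modules", {
  gm <- generate_modular(modular_spec(20, 16, n_modules = 3, p_in = 0.5,
                                      p_out = 0.05, seed = 4))
  cons <- consensus_runs(gm$net, n_runs = 8, sa_params(seed = 9))
  expect_gte(cons$selected_M, max(cons$runs$M) * 0.99 - 1e-12)
  near <- cons$runs[cons$runs$M >= max(cons$runs$M) * 0.99 - 1e-12, ]
  expect_equal(cons$selected$n_modules, min(near$n_modules))
})

test_that("normalised mutual information behaves as a similarity", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(7, 7, 5, 5, 9, 9)), 1)  # relabel-invariant
  expect_equal(nmi(a, rep(1, 6)), 0)
  expect_lt(nmi(a, c(1, 2, 3, 1, 2, 3)), 1)
})
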