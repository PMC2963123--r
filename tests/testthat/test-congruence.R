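test_that("leaf pairings enforce uniqueness and minimum size", {
  expect_error(leaf_pairing(c("a", "a"), c("x", "y")), "at most one pair")
  p3 <- leaf_pairing(paste0("a", 1:3), paste0("b", 1:3))
  t4 <- caterpillar_tree(paste0("a", 1:4))
  expect_error(robinson_foulds(t4, t4, p3), "at least 4")
})

test_that("RF distance separates identical and maximally different trees", {
  labs <- paste0("a", 1:6)
  tr <- caterpillar_tree(labs)
  pairing <- leaf_pairing(labs, labs)
  r <- robinson_foulds(tr, tr, pairing)
  expect_equal(r$rf, 0L)
  expect_equal(r$rf_normalized, 0)
  # the two distinct unrooted quartet topologies differ in their single split
  q1 <- ape::read.tree(text = "((a1:1,a2:1):1,(a3:1,a4:1):1);")
  q2 <- ape::read.tree(text = "((a1:1,a3:1):1,(a2:1,a4:1):1);")
  p4 <- leaf_pairing(paste0("a", 1:4), paste0("a", 1:4))
  r <- robinson_foulds(q1, q2, p4)
  expect_equal(r$rf, 2L)
  expect_equal(r$rf_normalized, 1)
})

test_that("RF agrees with the brute-force bipartition oracle", {
  set.seed(31)
  labs <- paste0("x", 1:6)
  pairing <- leaf_pairing(labs, labs)
  for (k in 1:50) {
    ta <- random_additive_case(6)$tree; ta$tip.label <- sample(labs)
    tb <- random_additive_case(6)$tree; tb$tip.label <- sample(labs)
    expect_equal(robinson_foulds(ta, tb, pairing)$rf,
                 brute_force_rf(ta, tb))
  }
})

test_that("pairing relabels before comparing, so leaf names may differ", {
  labs_a <- paste0("a", 1:6)
  labs_b <- paste0("b", 1:6)
  tr <- caterpillar_tree(labs_a)
  trb <- tr
  trb$tip.label <- sub("a", "b", trb$tip.label)
  expect_equal(robinson_foulds(tr, trb, leaf_pairing(labs_a, labs_b))$rf, 0L)
  # a scrambled pairing is a different mapping and scores > 0
  # (note: plain reversal would be an automorphism of the caterpillar)
  expect_gt(robinson_foulds(tr, trb,
                            leaf_pairing(labs_a,
                                         labs_b[c(4, 2, 3, 1, 5, 6)]))$rf, 0L)
})

test_that("cophenetic congruence is 1 for self and scale comparisons", {
  set.seed(32)
  tr <- random_additive_case(8)$tree
  pairing <- leaf_pairing(tr$tip.label, tr$tip.label)
  expect_equal(cophenetic_congruence(tr, tr, pairing), 1)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  expect_equal(cophenetic_congruence(tr, tr2, pairing), 1)
  # zero branch-length variance -> inconclusive sentinel
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  p4 <- leaf_pairing(letters[1:4], letters[1:4])
  expect_true(is.na(cophenetic_congruence(star, star, p4)))
})

test_that("independent trees score near zero congruence on average", {
  set.seed(33)
  r <- replicate(100, {
    sim <- simulate_coevolving_pair(
      sim_config(seed = sample.int(1e6, 1), mode = "independent"),
      sequences = FALSE)
    cophenetic_congruence(sim$tree_a, sim$tree_b, sim$pairing)
  })
  expect_lt(abs(mean(r)), 0.1)
})

test_that("permutation test calls congruent trees and validates inputs", {
  labs <- paste0("L", 1:8)
  tr <- caterpillar_tree(labs)
  pairing <- leaf_pairing(labs, labs)
  res <- permutation_test(tr, tr, pairing, n_perm = 999, seed = 99)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$verdict, "coevolved")
  expect_equal(res$cophenetic_r, 1)
  expect_gte(res$p_value, 1 / 1000)
  expect_error(permutation_test(tr, tr, pairing, n_perm = 10, seed = 1),
               "at least 99")
  expect_error(permutation_test(tr, tr, pairing[1:4, ], n_perm = 999,
                                seed = 1), "at least 5")
  expect_error(permutation_test(tr, tr, pairing, n_perm = 999), "seed")
  # reproducibility from the seed
  res2 <- permutation_test(tr, tr, pairing, n_perm = 999, seed = 99)
  expect_identical(res$p_value, res2$p_value)
})

test_that("null p-values are roughly uniform on independent trees", {
  set.seed(34)
  ps <- vapply(1:50, function(k) {
    sim <- simulate_coevolving_pair(
      sim_config(seed = 7000 + k, mode = "independent"), sequences = FALSE)
    permutation_test(sim$tree_a, sim$tree_b, sim$pairing, n_perm = 99,
                     seed = 8000 + k)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("paralogue ambiguity resolves to the most congruent pairing", {
  # tree B carries two paralogues for operon op1; b1 mirrors a1, b1x does not
  ta <- caterpillar_tree(paste0("a", 1:6))
  tb <- caterpillar_tree(c(paste0("b", 1:6), "b1x"))
  cand <- data.frame(
    leaf_a = c(paste0("a", 1:6), "a1"),
    leaf_b = c(paste0("b", 1:6), "b1x"),
    operon_id = c("op1", paste0("op", 2:6), "op1"),
    stringsAsFactors = FALSE)
  best <- select_best_pairing(ta, tb, cand)
  expect_true(attr(best, "post_hoc"))
  expect_equal(nrow(best), 6L)
  expect_equal(best$leaf_b[best$leaf_a == "a1"], "b1")
  # the chosen pairing strictly beats the paralogous alternative
  alt <- leaf_pairing(paste0("a", 1:6), c("b1x", paste0("b", 2:6)))
  expect_gt(attr(best, "cophenetic_r"),
            cophenetic_congruence(ta, tb, alt))
})
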