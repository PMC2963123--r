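test_that("sequence evolution respects rate, mask, and seed", {
  tr <- ape::read.tree(text = "(a:0.5,b:0);")
  root <- paste(rep("A", 200), collapse = "")
  # rate 0: all leaves identical to the root
  leaves <- evolve_sequences(tr, root, rate = 0, seed = 61)
  expect_true(all(leaves == root))
  # masked positions never change
  set.seed(62)
  mask <- 1:12
  tr2 <- random_tree(6, branch_mean = 0.5)
  root2 <- random_protein(100)
  leaves2 <- evolve_sequences(tr2, root2, rate = 2, invariant_mask = mask,
                              seed = 63)
  for (s in leaves2)
    expect_equal(substr(s, 1, 12), substr(root2, 1, 12))
  expect_error(evolve_sequences(tr2, root2, invariant_mask = 200, seed = 1),
               "invariant_mask")
  # determinism
  expect_identical(evolve_sequences(tr2, root2, seed = 64),
                   evolve_sequences(tr2, root2, seed = 64))
})

test_that("substitution fraction follows 1 - exp(-rt) on a single branch", {
  t_br <- 0.4; rate <- 1
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0);", t_br))
  L <- 10000L
  set.seed(65)
  root <- random_protein(L)
  leaves <- evolve_sequences(tr, root, rate = rate, seed = 66)
  # leaf b sits at distance 0, so it is the root; compare a against it
  diff_frac <- mean(strsplit(leaves[["a"]], "")[[1]] !=
                      strsplit(leaves[["b"]], "")[[1]])
  p <- 1 - exp(-rate * t_br)
  ci <- qbinom(c(0.005, 0.995), L, p) / L
  expect_gte(diff_frac, ci[1])
  expect_lte(diff_frac, ci[2])
})

test_that("coevolving-pair simulation matches its declared mode", {
  # shared mode with zero jitter: identical topologies
  sim0 <- simulate_coevolving_pair(
    sim_config(seed = 67, branch_jitter_sigma = 0), sequences = FALSE)
  expect_equal(robinson_foulds(sim0$tree_a, sim0$tree_b, sim0$pairing)$rf, 0L)
  # byte-identical reruns from the same seed
  cfg <- sim_config(seed = 68, root_len = 80)
  expect_identical(simulate_coevolving_pair(cfg), simulate_coevolving_pair(cfg))
  expect_error(simulate_coevolving_pair(sim_config(seed = 1, n_taxa = 4)),
               "n_taxa")
  # independent topologies share almost no bipartitions
  nrf <- vapply(1:100, function(k) {
    sim <- simulate_coevolving_pair(
      sim_config(seed = 5000 + k, mode = "independent", n_taxa = 16),
      sequences = FALSE)
    robinson_foulds(sim$tree_a, sim$tree_b, sim$pairing)$rf_normalized
  }, numeric(1))
  expect_gte(mean(nrf), 0.9)
})

test_that("genome simulation honours counts, templates, and bounds", {
  g1 <- simulate_genomes(sim_config(seed = 69, n_genomes = 1,
                                    templates = list(x = c("arsA", "cstA",
                                                           "cstX")),
                                    template_prob = c(x = 1),
                                    elsewhere_prob = 0))
  ops <- call_operons(g1$features, max_gap = 200)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$families, "arsA,cstA,cstX")
  expect_equal(ops$loci, g1$operons_truth$loci)
  g0 <- simulate_genomes(sim_config(seed = 70, n_genomes = 0))
  expect_equal(nrow(g0$features), 0L)
  expect_equal(nrow(g0$operons_truth), 0L)
})

test_that("end-to-end recovery: sequences to verdicts at the stated rates", {
  # shared trees, sigma 0.1, 12 pairs: the pipeline distance -> NJ ->
  # permutation route must reject in at least 90% of 50 seeded replicates
  # (root length 200 aa keeps the suite inside its time budget)
  run_one <- function(seed_sim, seed_test, mode) {
    sim <- simulate_coevolving_pair(
      sim_config(seed = seed_sim, mode = mode, root_len = 200,
                 branch_jitter_sigma = 0.1))
    ta <- neighbor_joining(pairwise_distances(sim$seq_a)$distance)
    tb <- neighbor_joining(pairwise_distances(sim$seq_b)$distance)
    permutation_test(ta, tb, sim$pairing, n_perm = 199,
                     seed = seed_test)$p_value <= 0.05
  }
  shared <- vapply(1:50, function(k)
    run_one(300 + k, 900 + k, "shared_tree"), logical(1))
  expect_gte(mean(shared), 0.9)
  # independent data: rejection rate compatible with the nominal 5%
  indep <- vapply(1:50, function(k)
    run_one(1300 + k, 1900 + k, "independent"), logical(1))
  expect_lte(sum(indep), qbinom(0.975, 50, 0.05))
})
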