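feat_row <- function(genome, contig, start, end, strand, family, locus) {
  data.frame(genome = genome, contig = contig, start = start, end = end,
             strand = strand, family = family, locus = locus,
             stringsAsFactors = FALSE)
}

test_that("the intergenic-gap rule groups and splits genes", {
  two <- rbind(feat_row("g1", "c1", 1, 900, "+", "arsA", "l1"),
               feat_row("g1", "c1", 951, 1800, "+", "arsB", "l2"))
  ops <- call_operons(two, max_gap = 200)
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 2L)
  expect_equal(ops$loci, "l1,l2")
  # gap of 500 splits them
  far <- two
  far$start[2] <- 1401; far$end[2] <- 2300
  ops <- call_operons(far, max_gap = 200)
  expect_equal(nrow(ops), 2L)
  expect_true(all(ops$n_genes == 1L))
  # opposite strands split when required, merge when not
  mixed <- two
  mixed$strand[2] <- "-"
  expect_equal(nrow(call_operons(mixed, max_gap = 200)), 2L)
  expect_equal(nrow(call_operons(mixed, max_gap = 200,
                                 require_same_strand = FALSE)), 1L)
  # overlapping same-strand genes stay together
  over <- rbind(feat_row("g1", "c1", 1, 900, "+", "arsA", "l1"),
                feat_row("g1", "c1", 850, 1700, "+", "arsB", "l2"))
  expect_equal(nrow(call_operons(over, max_gap = 200)), 1L)
})

test_that("feature validation catches malformed tables", {
  bad <- feat_row("g1", "c1", 100, 50, "+", "arsA", "l1")
  expect_error(call_operons(bad), "coordinates")
  badstrand <- feat_row("g1", "c1", 1, 50, "*", "arsA", "l1")
  expect_error(call_operons(badstrand), "strand")
  expect_error(call_operons(data.frame(genome = "g")), "missing column")
})

test_that("operon calling is idempotent and order-invariant", {
  g <- simulate_genomes(sim_config(seed = 81, n_genomes = 5))
  ops1 <- call_operons(g$features)
  ops2 <- call_operons(g$features[sample(nrow(g$features)), ])
  expect_identical(ops1, ops2)
  # every gene in exactly one operon
  all_loci <- sort(unlist(strsplit(ops1$loci, ",")))
  expect_identical(all_loci, sort(g$features$locus))
})

test_that("association profiles implement the three-way bookkeeping", {
  feats <- rbind(
    # genome A: arsA and acr3 co-operonic
    feat_row("gA", "c1", 1, 900, "+", "arsA", "a1"),
    feat_row("gA", "c1", 951, 1800, "+", "acr3", "a2"),
    # genome B: both present, different contigs
    feat_row("gB", "c1", 1, 900, "+", "arsA", "b1"),
    feat_row("gB", "c2", 1, 900, "+", "acr3", "b2"),
    # genome C: arsA only
    feat_row("gC", "c1", 1, 900, "+", "arsA", "c1"))
  prof <- association_profile(feats, "arsA", "acr3")
  expect_equal(prof$n_same_operon, 1L)
  expect_equal(prof$n_elsewhere_in_genome, 1L)
  expect_equal(prof$n_absent, 1L)
  # the counts partition the family-A genomes
  expect_equal(prof$n_same_operon + prof$n_elsewhere_in_genome +
                 prof$n_absent, nrow(prof$per_genome))
  # excluding arsB drops a genome carrying it anywhere
  feats2 <- rbind(feats, feat_row("gA", "c2", 1, 600, "+", "arsB", "a3"))
  prof2 <- association_profile(feats2, "arsA", "acr3", exclude = "arsB")
  expect_equal(prof2$n_same_operon, 0L)
  expect_false("gA" %in% prof2$per_genome$genome)
  expect_warning(association_profile(feats, "nope", "acr3"), "absent")
})

test_that("operon pairing emits one pair per co-operonic occurrence", {
  one <- rbind(feat_row("g1", "c1", 1, 900, "+", "arsA", "g1A"),
               feat_row("g1", "c1", 951, 1800, "+", "cstA", "g1C"))
  p <- operon_pairing(one, "arsA", "cstA")
  expect_s3_class(p, "leaf_pairing")
  expect_equal(p$leaf_a, "g1A")
  expect_equal(p$leaf_b, "g1C")
  # two operons in one genome -> two pairs
  two <- rbind(one,
               feat_row("g1", "c1", 20001, 20900, "+", "arsA", "g1A2"),
               feat_row("g1", "c1", 20951, 21800, "+", "cstA", "g1C2"))
  p2 <- operon_pairing(two, "arsA", "cstA")
  expect_equal(nrow(p2), 2L)
  expect_equal(length(unique(p2$operon_id)), 2L)
  # paralogues within one operon -> candidate table for select_best_pairing
  para <- rbind(one, feat_row("g1", "c1", 1851, 2700, "+", "cstA", "g1C1b"))
  pc <- operon_pairing(para, "arsA", "cstA")
  expect_equal(nrow(pc), 2L)
  expect_equal(length(unique(pc$operon_id)), 1L)
  # no co-operonic genomes -> empty pairing
  expect_equal(nrow(operon_pairing(one, "arsA", "gvpN")), 0L)
})

test_that("context leaf names follow the organism/paralogue convention", {
  expect_equal(context_leaf_name("Aaa", 1), "Aaa1")
  expect_equal(context_leaf_name("Aaa", 1, 2), "Aaa1-2")
  expect_equal(context_leaf_name("Aaa", 1, 3, elsewhere = TRUE), "Aaa1-3E")
})

test_that("simulated genomes round-trip through operon calling", {
  g <- simulate_genomes(sim_config(seed = 82, n_genomes = 8))
  ops <- call_operons(g$features, max_gap = 200)
  called <- ops$loci
  for (k in seq_len(nrow(g$operons_truth))) {
    expect_true(g$operons_truth$loci[k] %in% called,
                info = paste("planted operon", k, "not recovered"))
  }
  # association classes agree with the generator's own bookkeeping
  for (fb in c("arsB", "acr3", "cstA")) {
    truth <- g$association_truth("arsA", fb)
    prof <- association_profile(g$features, "arsA", fb)
    got <- prof$per_genome
    expect_equal(got[order(got$genome), ],
                 truth[order(truth$genome), ],
                 ignore_attr = TRUE, info = fb)
  }
  # planted pairing equals the called pairing
  truth_pairs <- g$pairing_truth("arsA", "cstA")
  called_pairs <- operon_pairing(g$features, "arsA", "cstA")
  expect_setequal(paste(truth_pairs$leaf_a, truth_pairs$leaf_b),
                  paste(called_pairs$leaf_a, called_pairs$leaf_b))
})
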