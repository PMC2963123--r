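test_that("self-alignment scores the BLOSUM62 diagonal and identity 1", {
  al <- global_align("ACDE", "ACDE")
  # A=4, C=9, D=6, E=5 on the published BLOSUM62 diagonal
  expect_equal(al$score, 24)
  expect_equal(al$identity, 1)
  expect_equal(al$aligned_a, "ACDE")
  expect_equal(al$aligned_b, "ACDE")
})

test_that("empty and illegal inputs are handled", {
  al <- global_align("", "")
  expect_equal(al$score, 0)
  expect_equal(al$aligned_a, "")
  expect_error(global_align("AC1E", "ACDE"), "illegal residue")
})

test_that("DP score equals brute-force enumeration on short sequences", {
  set.seed(7)
  scheme <- scoring_scheme()
  reduced <- c("A", "C", "D", "E")
  for (k in 1:40) {
    a <- random_protein(sample(0:4, 1), reduced)
    b <- random_protein(sample(0:4, 1), reduced)
    if (nchar(a) == 0 && nchar(b) == 0) next
    expect_equal(global_align(a, b, scheme)$score,
                 brute_force_align_score(a, b, scheme),
                 info = paste(a, "vs", b))
  }
})

test_that("alignment round-trips its inputs and identity skips terminal gaps", {
  set.seed(8)
  for (k in 1:10) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    # no gap-gap columns
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
  # an exact internal fragment scores identity 1 over the overlap
  full <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  frag <- substr(full, 8, 25)
  expect_equal(global_align(full, frag)$identity, 1)
})

test_that("poisson distance is the clamped -log identity", {
  expect_equal(poisson_distance(1), 0)
  expect_equal(poisson_distance(0.5), 0.6931, tolerance = 1e-4)
  expect_warning(d0 <- poisson_distance(0), "capped")
  expect_equal(d0, 10)
  expect_error(poisson_distance(1.2), "identity")
  # monotone bijection on (0, 1]
  ids <- seq(0.05, 1, by = 0.05)
  d <- poisson_distance(ids)
  expect_true(all(diff(d) < 0))
  expect_equal(exp(-d), ids, tolerance = 1e-12)
})

test_that("score distance is a symmetric premetric correlating with poisson", {
  set.seed(9)
  a <- random_protein(50)
  b <- random_protein(50)
  expect_equal(score_distance(a, a), 0)
  expect_equal(score_distance(a, b), score_distance(b, a))
  # on a simulated family, ranks agree with the poisson distance
  root <- random_protein(80)
  fam <- vapply(c(2, 6, 12, 20, 30), function(k) mutate_seq(root, k),
                character(1))
  sd_ <- vapply(fam, function(s) score_distance(root, s), numeric(1))
  pd_ <- vapply(fam, function(s)
    poisson_distance(global_align(root, s)$identity), numeric(1))
  expect_gt(cor(sd_, pd_, method = "spearman"), 0.8)
})

test_that("progressive MSA reduces correctly and confines planted indels", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  m3 <- progressive_msa(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", m3$rows)))
  expect_equal(m3$ncol, nchar(s))
  # two sequences: identical to the pairwise aligner
  set.seed(10)
  x <- random_protein(30); y <- random_protein(25)
  m2 <- progressive_msa(c(x = x, y = y))
  al <- global_align(x, y)
  expect_equal(unname(m2$rows["x"]), al$aligned_a)
  expect_equal(unname(m2$rows["y"]), al$aligned_b)
  # planted 5-residue insertion -> one 5-column gap block in all other rows
  set.seed(11)
  base <- random_protein(60)
  fam <- c(s1 = base, s2 = mutate_seq(base, 2),
           s3 = paste0(substr(base, 1, 30), "WWWWW", substr(base, 31, 60)),
           s4 = mutate_seq(base, 3))
  m <- progressive_msa(fam)
  expect_gte(m$ncol, 65L)
  for (id in c("s1", "s2", "s4")) {
    gaps <- gregexpr("-+", m$rows[[id]])[[1]]
    expect_equal(sum(attr(gaps, "match.length")), 5L)
  }
  # every row ungaps to its input
  for (id in names(fam)) expect_equal(gsub("-", "", m$rows[[id]]),
                                      unname(fam[id]))
})

test_that("reference positions map onto MSA columns", {
  m <- structure(list(ids = c("r", "s"),
                      rows = c(r = "A-CD", s = "ABCD"), ncol = 4L),
                 class = "msa")
  expect_equal(map_reference_column(m, "r", 1), 0L)
  expect_equal(map_reference_column(m, "r", 2), 2L)
  expect_equal(map_reference_column(m, "r", 3), 3L)
  expect_error(map_reference_column(m, "r", 4), "beyond ungapped length")
  expect_error(map_reference_column(m, "zz", 1), "not in MSA")
  # agreement with a literal scan oracle on random gapped rows
  set.seed(12)
  for (k in 1:10) {
    ch <- sample(c(AA20, "-", "-"), 30, replace = TRUE)
    if (all(ch == "-")) next
    m <- structure(list(ids = "r",
                        rows = c(r = paste(ch, collapse = "")), ncol = 30L),
                   class = "msa")
    nong <- which(ch != "-")
    for (p in seq_along(nong)) {
      expect_equal(map_reference_column(m, "r", p), nong[p] - 1L)
    }
  }
})
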