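#' Simulation configuration
#'
#' Bundles the knobs of the two simulators with the defaults used throughout
#' the test-suite: 12 taxa, shared topology with branch-length jitter sigma
#' 0.1, substitution rate 1 per unit branch length, 300-residue root
#' sequences, exponential branch lengths of mean 0.3 substitutions/site, and
#' operon templates mirroring the three genomic contexts the family occurs
#' in (classic arsenical-resistance operons, carbon-starvation operons, and
#' gas-vesicle gene clusters).
#'
#' @param n_taxa Number of taxa / leaf pairs (>= 2; coevolution simulations
#'   need >= 5).
#' @param mode `"shared_tree"` (coevolving) or `"independent"`.
#' @param branch_jitter_sigma Lognormal sigma applied per branch to the B
#'   family's lengths in shared mode.
#' @param rate Substitution rate per unit branch length.
#' @param root_len Root sequence length in residues.
#' @param invariant_mask Integer positions held invariant in every lineage
#'   (e.g. a planted motif).
#' @param branch_mean Mean of the exponential branch-length distribution.
#' @param templates List of ordered family-label vectors planted as operons.
#' @param template_prob Per-template inclusion probability per genome.
#' @param n_genomes Number of genomes to simulate.
#' @param gap_bounds Intra-operon intergenic gap bounds in bp.
#' @param gene_len_bounds Gene length bounds in bp.
#' @param elsewhere_prob Probability that a genome carrying family
#'   `elsewhere_family` via no template still receives a solitary copy far
#'   from any operon.
#' @param elsewhere_family Family label used for "elsewhere" placements.
#' @param seed Integer seed; mandatory.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 12L,
                       mode = c("shared_tree", "independent"),
                       branch_jitter_sigma = 0.1,
                       rate = 1,
                       root_len = 300L,
                       invariant_mask = integer(0),
                       branch_mean = 0.3,
                       templates = list(
                         ars = c("arsR", "arsD", "arsA", "arsB"),
                         acr = c("arsR", "arsA", "acr3"),
                         cst = c("arsA", "cstA", "cstX", "cstY"),
                         gvp = c("gvpN", "gvpL", "gvpF", "arsA")),
                       template_prob = c(ars = 0.6, acr = 0.3, cst = 0.4,
                                         gvp = 0.2),
                       n_genomes = 10L,
                       gap_bounds = c(0L, 100L),
                       gene_len_bounds = c(300L, 1500L),
                       elsewhere_prob = 0.3,
                       elsewhere_family = "acr3",
                       seed) {
  if (missing(seed)) stop("seed is required")
  mode <- match.arg(mode)
  stopifnot(n_taxa >= 2L, branch_jitter_sigma >= 0, rate >= 0, root_len >= 1L,
            branch_mean > 0, gap_bounds[1L] >= 0L,
            gap_bounds[2L] >= gap_bounds[1L],
            gene_len_bounds[1L] >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

#' Random tree with exponential branch lengths
#'
#' Random (Yule-like pure-birth) topology with i.i.d. exponential branch
#' lengths, the stated simulation ground truth for tree-signal tests.
#'
#' @param n_taxa Number of leaves.
#' @param branch_mean Mean branch length (default 0.3).
#' @param labels Optional tip labels (default `t1..tn`).
#' @return A rooted `ape::phylo`.
#' @export
random_tree <- function(n_taxa, branch_mean = 0.3, labels = NULL) {
  tr <- ape::rtree(n_taxa, rooted = TRUE,
                   br = function(n) rexp(n, rate = 1 / branch_mean))
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  # assign labels to tips uniformly at random: rtree numbers tips in
  # cladewise order, which would correlate label order with tree position
  # (and, across two independent trees, label with label)
  tr$tip.label <- labels[sample.int(n_taxa)]
  tr
}

#' Evolve protein sequences along a tree
#'
#' Poisson substitution process: along a branch of length `t` each
#' non-invariant site substitutes with probability `1 - exp(-rate * t)`; the
#' replacement residue is drawn from the background frequencies excluding the
#' current residue. No indels are generated, so leaf sequences stay aligned
#' column-for-column to the root.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param root_seq Root protein sequence (string).
#' @param rate Substitution rate per unit branch length.
#' @param invariant_mask 1-based positions never substituted.
#' @param seed Integer seed.
#' @param background Residue frequencies for replacements (default uniform
#'   over the 20 standard residues).
#' @return Named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, root_seq, rate = 1,
                             invariant_mask = integer(0), seed,
                             background = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  root_vec <- match(strsplit(toupper(root_seq), "")[[1]], .AA20)
  if (anyNA(root_vec)) stop("root_seq must use the 20 standard residues")
  L <- length(root_vec)
  if (length(invariant_mask) &&
      (min(invariant_mask) < 1L || max(invariant_mask) > L))
    stop("invariant_mask outside sequence (length ", L, ")")
  bg <- if (is.null(background)) rep(1 / 20, 20) else background / sum(background)
  mutable <- setdiff(seq_len(L), invariant_mask)
  set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- root_vec
  # preorder over edges (ape trees store edges parent-before-child after
  # reorder)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    t <- tr$edge.length[k]
    s <- seqs[[par]]
    p_sub <- 1 - exp(-rate * t)
    hit <- mutable[runif(length(mutable)) < p_sub]
    for (pos in hit) {
      w <- bg
      w[s[pos]] <- 0
      s[pos] <- sample.int(20L, 1L, prob = w)
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(.AA20[seqs[[i]]], collapse = ""), character(1))
  setNames(out, tree$tip.label)
}

#' Simulate a coevolving (or independent) pair of protein families
#'
#' In `shared_tree` mode both families evolve on one topology; the B family's
#' branch lengths are the A family's multiplied per branch by
#' `exp(N(0, sigma^2))`, emulating correlated but rate-jittered evolution.
#' In `independent` mode the two families get unrelated random topologies.
#' Sequences are evolved with [evolve_sequences()]; the true pairing is the
#' taxon identity map.
#'
#' @param config A [sim_config()].
#' @param sequences Evolve sequences too (default TRUE); with FALSE only the
#'   generating trees and pairing are returned (cheap, for tree-level tests).
#' @return List: `seq_a`, `seq_b` (or NULL), `pairing` ([leaf_pairing()]),
#'   `tree_a`, `tree_b`, `mode`.
#' @export
simulate_coevolving_pair <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_taxa < 5L) stop("need n_taxa >= 5")
  set.seed(as.integer(config$seed))
  labs <- sprintf("t%02d", seq_len(config$n_taxa))
  tree_a <- random_tree(config$n_taxa, config$branch_mean, labs)
  if (config$mode == "shared_tree") {
    tree_b <- tree_a
    jit <- exp(rnorm(length(tree_b$edge.length), 0,
                     config$branch_jitter_sigma))
    tree_b$edge.length <- tree_b$edge.length * jit
  } else {
    tree_b <- random_tree(config$n_taxa, config$branch_mean, labs)
  }
  tree_b$tip.label <- sub("^t", "b", tree_b$tip.label)
  seq_a <- seq_b <- NULL
  if (sequences) {
    root_a <- paste(sample(.AA20, config$root_len, replace = TRUE),
                    collapse = "")
    root_b <- paste(sample(.AA20, config$root_len, replace = TRUE),
                    collapse = "")
    seed_a <- sample.int(.Machine$integer.max, 1L)
    seed_b <- sample.int(.Machine$integer.max, 1L)
    seq_a <- evolve_sequences(tree_a, root_a, config$rate,
                              config$invariant_mask, seed_a)
    seq_b <- evolve_sequences(tree_b, root_b, config$rate,
                              config$invariant_mask, seed_b)
  }
  list(seq_a = seq_a, seq_b = seq_b,
       pairing = leaf_pairing(labs, sub("^t", "b", labs)),
       tree_a = tree_a, tree_b = tree_b, mode = config$mode)
}

#' Simulate operon-structured genome annotation tables
#'
#' Each genome receives each operon template independently with its
#' configured probability (at least one template per genome is forced so no
#' genome is empty). Genes get lengths and intra-operon gaps drawn uniformly
#' within the configured bounds; successive operons are separated by much
#' more than any plausible `max_gap` (10 kb). With probability
#' `elsewhere_prob`, a genome that did not receive `elsewhere_family` in any
#' template gets a solitary copy on a second contig - an "elsewhere in
#' genome" placement. The returned truth record lists every planted operon
#' and, for every ordered family pair occurring in the simulation, the
#' per-genome association class computed from the plant itself (independent
#' of [call_operons()] / [association_profile()]).
#'
#' @param config A [sim_config()].
#' @return List: `features` (gene table), `operons_truth` (planted operons),
#'   `association_truth` (function(family_a, family_b) -> per-genome class
#'   data.frame), `pairing_truth` (function(family_a, family_b) ->
#'   [leaf_pairing()] of planted co-operonic loci).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_genomes)
  feats <- list(); truth <- list()
  if (n > 0L) for (g in seq_len(n)) {
    genome <- sprintf("G%03d", g)
    take <- runif(length(config$templates)) < config$template_prob
    if (!any(take)) take[sample.int(length(take), 1L)] <- TRUE
    pos <- 1L
    locus_n <- 0L
    for (ti in which(take)) {
      fams <- config$templates[[ti]]
      strand <- sample(c("+", "-"), 1L)
      op_rows <- list()
      for (f in fams) {
        len <- sample(seq(config$gene_len_bounds[1L],
                          config$gene_len_bounds[2L]), 1L)
        locus_n <- locus_n + 1L
        op_rows[[f]] <- data.frame(
          genome = genome, contig = "c1", start = pos, end = pos + len - 1L,
          strand = strand, family = f,
          locus = sprintf("%s_%03d_%s", genome, locus_n, f),
          stringsAsFactors = FALSE)
        gap <- sample(seq(config$gap_bounds[1L], config$gap_bounds[2L]), 1L)
        pos <- pos + len + gap
      }
      op <- do.call(rbind, op_rows)
      feats[[length(feats) + 1L]] <- op
      truth[[length(truth) + 1L]] <- data.frame(
        genome = genome, template = names(config$templates)[ti],
        families = paste(fams, collapse = ","),
        loci = paste(op$locus, collapse = ","), stringsAsFactors = FALSE)
      pos <- pos + 10000L  # inter-operon spacer far above any max_gap
    }
    planted_fams <- unlist(lapply(feats[vapply(feats, function(x)
      x$genome[1L] == genome, logical(1))], function(x) x$family))
    if (!(config$elsewhere_family %in% planted_fams) &&
        runif(1) < config$elsewhere_prob) {
      len <- sample(seq(config$gene_len_bounds[1L],
                        config$gene_len_bounds[2L]), 1L)
      locus_n <- locus_n + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        genome = genome, contig = "c2", start = 1L, end = len,
        strand = "+", family = config$elsewhere_family,
        locus = sprintf("%s_%03d_%s", genome, locus_n,
                        config$elsewhere_family),
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(genome = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               family = character(0), locus = character(0))
  rownames(features) <- NULL
  operons_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome = character(0), template = character(0),
               families = character(0), loci = character(0))

  association_truth <- function(family_a, family_b) {
    gens <- unique(features$genome[features$family == family_a])
    cls <- vapply(gens, function(gn) {
      ops <- operons_truth[operons_truth$genome == gn, , drop = FALSE]
      fam_lists <- strsplit(ops$families, ",", fixed = TRUE)
      if (any(vapply(fam_lists, function(f)
        family_a %in% f && family_b %in% f, logical(1)))) "same_operon"
      else if (family_b %in% features$family[features$genome == gn])
        "elsewhere_in_genome"
      else "absent"
    }, character(1))
    data.frame(genome = gens, class = unname(cls), stringsAsFactors = FALSE)
  }

  pairing_truth <- function(family_a, family_b) {
    la <- character(0); lb <- character(0); op <- character(0)
    for (k in seq_len(nrow(operons_truth))) {
      fams <- strsplit(operons_truth$families[k], ",", fixed = TRUE)[[1]]
      loci <- strsplit(operons_truth$loci[k], ",", fixed = TRUE)[[1]]
      ia <- which(fams == family_a); ib <- which(fams == family_b)
      if (length(ia) == 1L && length(ib) == 1L) {
        la <- c(la, loci[ia]); lb <- c(lb, loci[ib])
        op <- c(op, sprintf("truth_op%03d", k))
      }
    }
    leaf_pairing(la, lb, op)
  }

  list(features = features, operons_truth = operons_truth,
       association_truth = association_truth, pairing_truth = pairing_truth)
}
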