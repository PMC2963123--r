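#' Run the full analysis pipeline
#'
#' Orchestrates the stages filter -> align/distances -> trees -> pairing ->
#' congruence (plus motif discovery on the A family) from one configuration,
#' writing every intermediate artifact and a manifest of MD5 hashes so a rerun
#' with the same inputs and seed is byte-identical. The configuration either
#' names input files (`fasta_a`, `fasta_b`, `pairs`) or requests simulation
#' (`simulate = TRUE`), in which case no external files are needed.
#'
#' Configuration keys (list or `key = value` text file):
#' `simulate` (logical), `seed` (integer, required), `n_taxa`, `mode`,
#' `sigma`, `root_len`, `fasta_a`, `fasta_b`, `pairs` (TSV
#' `leaf_a leaf_b [operon_id]`), `cutoff` (redundancy filter; NA skips),
#' `n_perm`, `alpha`, `motif_width` (NA skips motif discovery).
#'
#' @param config List or path to a `key = value` configuration file.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the stage results and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  defaults <- list(simulate = TRUE, n_taxa = 12L, mode = "shared_tree",
                   sigma = 0.1, root_len = 200L, cutoff = NA, n_perm = 999L,
                   alpha = 0.05, motif_width = NA, fasta_a = NA, fasta_b = NA,
                   pairs = NA)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed)) stop("pipeline config requires a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }
  fail <- function(stage, msg) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", msg),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }

  # --- stage: inputs -------------------------------------------------------
  if (isTRUE(cfg$simulate) || identical(cfg$simulate, "TRUE")) {
    sc <- sim_config(n_taxa = as.integer(cfg$n_taxa), mode = cfg$mode,
                     branch_jitter_sigma = as.numeric(cfg$sigma),
                     root_len = as.integer(cfg$root_len),
                     seed = as.integer(cfg$seed))
    sim <- simulate_coevolving_pair(sc)
    seq_a <- sim$seq_a; seq_b <- sim$seq_b; pairing <- sim$pairing
    emit("family_a.fasta", function(p) write_fasta(seq_a, p))
    emit("family_b.fasta", function(p) write_fasta(seq_b, p))
    emit("generating_tree_a.nwk",
         function(p) ape::write.tree(sim$tree_a, file = p))
    emit("generating_tree_b.nwk",
         function(p) ape::write.tree(sim$tree_b, file = p))
  } else {
    for (f in c("fasta_a", "fasta_b", "pairs"))
      if (is.na(cfg[[f]]) || !file.exists(cfg[[f]]))
        fail("inputs", paste0("missing input file for '", f, "': ", cfg[[f]]))
    seq_a <- read_fasta(cfg$fasta_a)
    seq_b <- read_fasta(cfg$fasta_b)
    pr <- read.delim(cfg$pairs, header = TRUE, stringsAsFactors = FALSE)
    pairing <- leaf_pairing(pr$leaf_a, pr$leaf_b,
                            if ("operon_id" %in% names(pr)) pr$operon_id)
  }

  # --- stage: redundancy filter -------------------------------------------
  if (!is.na(cfg$cutoff)) {
    seq_a <- filter_redundant(seq_a, as.numeric(cfg$cutoff))
    seq_b <- filter_redundant(seq_b, as.numeric(cfg$cutoff))
    pairing <- pairing[pairing$leaf_a %in% names(seq_a) &
                         pairing$leaf_b %in% names(seq_b), ]
    emit("family_a.filtered.fasta", function(p) write_fasta(seq_a, p))
    emit("family_b.filtered.fasta", function(p) write_fasta(seq_b, p))
  }

  # --- stage: distances and trees -----------------------------------------
  if (length(seq_a) < 4L || length(seq_b) < 4L)
    fail("distances", "fewer than 4 sequences per family after filtering")
  da <- pairwise_distances(seq_a)$distance
  db <- pairwise_distances(seq_b)$distance
  emit("dist_a.tsv", function(p) write_distance_tsv(da, p))
  emit("dist_b.tsv", function(p) write_distance_tsv(db, p))
  tree_a <- neighbor_joining(da)
  tree_b <- neighbor_joining(db)
  emit("tree_a.nwk", function(p) ape::write.tree(tree_a, file = p))
  emit("tree_b.nwk", function(p) ape::write.tree(tree_b, file = p))

  # --- stage: congruence ---------------------------------------------------
  cong <- permutation_test(tree_a, tree_b, pairing,
                           n_perm = as.integer(cfg$n_perm),
                           seed = as.integer(cfg$seed),
                           alpha = as.numeric(cfg$alpha))
  emit("congruence.json", function(p)
    jsonlite::write_json(unclass(cong), p, auto_unbox = TRUE, digits = NA))

  # --- stage: motif --------------------------------------------------------
  motif <- NULL
  if (!is.na(cfg$motif_width)) {
    motif <- discover_motif_em(unname(seq_a),
                               width = as.integer(cfg$motif_width),
                               seed = as.integer(cfg$seed))
    emit("motif_a.tsv", function(p)
      write.table(data.frame(position = seq_len(motif$width),
                             consensus = strsplit(motif$consensus_plain,
                                                  "")[[1]],
                             ic_bits = motif$ic, motif$freq),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  # --- manifest ------------------------------------------------------------
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(congruence = cong, motif = motif, manifest = manifest,
                 tree_a = tree_a, tree_b = tree_b, out_dir = out_dir))
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line ", bad[1L], ": ", lines[bad[1L]])
  vals <- lapply(kv, function(x) {
    v <- x[2L]
    if (grepl("^-?[0-9.]+$", v)) as.numeric(v)
    else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  })
  setNames(vals, vapply(kv, `[`, character(1), 1L))
}
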