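#' Read a genome feature table
#'
#' Feature tables are the offline stand-in for a comparative-genomics database:
#' one row per annotated gene with a family label assigned upstream. Columns:
#' `genome`, `contig`, `start`, `end` (1-based inclusive), `strand` (`+`/`-`),
#' `family`, `locus`.
#'
#' @param path TSV file path.
#' @return Validated data.frame of gene features.
#' @export
read_features <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_features(d)
}

validate_features <- function(d) {
  req <- c("genome", "contig", "start", "end", "strand", "family", "locus")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  if (anyNA(d$start) || anyNA(d$end) || any(d$start < 1L) ||
      any(d$start > d$end))
    stop("malformed coordinates: need 1 <= start <= end")
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(d$locus)) stop("locus ids must be unique")
  d[, req]
}

#' Delineate operons from gene features
#'
#' Surrogate operon rule: within a contig, a maximal run of genes on the same
#' strand whose consecutive intergenic gaps are at most `max_gap` bp forms one
#' operon; every gene belongs to exactly one operon (possibly a singleton).
#' Overlapping same-strand genes (negative gap) stay together. The 200 bp
#' default is the standard prokaryotic intergenic-distance heuristic.
#'
#' @param features Feature data.frame (see [read_features()]); sorted
#'   internally per contig by start.
#' @param max_gap Maximum intergenic gap in bp (default 200).
#' @param require_same_strand Split runs at strand switches (default TRUE).
#' @return Data.frame with one row per operon: `operon_id`, `genome`,
#'   `contig`, `strand`, `n_genes`, `loci` (comma-joined, in genomic order),
#'   `families` (comma-joined).
#' @export
call_operons <- function(features, max_gap = 200L, require_same_strand = TRUE) {
  d <- validate_features(features)
  d <- d[order(d$genome, d$contig, d$start, d$end, d$locus), ]
  n <- nrow(d)
  if (n == 0L)
    return(data.frame(operon_id = character(0), genome = character(0),
                      contig = character(0), strand = character(0),
                      n_genes = integer(0), loci = character(0),
                      families = character(0), stringsAsFactors = FALSE))
  newblock <- c(TRUE, d$genome[-1L] != d$genome[-n] |
                  d$contig[-1L] != d$contig[-n])
  gap <- c(NA_integer_, d$start[-1L] - d$end[-n] - 1L)
  brk <- newblock | gap > max_gap
  if (require_same_strand)
    brk <- brk | c(TRUE, d$strand[-1L] != d$strand[-n])
  grp <- cumsum(brk)
  sp <- split(seq_len(n), grp)
  out <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(genome = d$genome[ix[1L]], contig = d$contig[ix[1L]],
               strand = if (require_same_strand) d$strand[ix[1L]] else
                 paste(unique(d$strand[ix]), collapse = "/"),
               n_genes = length(ix),
               loci = paste(d$locus[ix], collapse = ","),
               families = paste(d$family[ix], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$operon_id <- sprintf("%s_op%03d", out$genome,
                           as.integer(stats::ave(seq_len(nrow(out)),
                                                 out$genome, FUN = seq_along)))
  rownames(out) <- NULL
  out[, c("operon_id", "genome", "contig", "strand", "n_genes", "loci",
          "families")]
}

operon_families <- function(operons) strsplit(operons$families, ",", fixed = TRUE)
operon_loci <- function(operons) strsplit(operons$loci, ",", fixed = TRUE)

#' Genome-context association profile of two gene families
#'
#' Classifies every genome containing `family_a` into one of three mutually
#' exclusive classes: `same_operon` (some operon carries both families),
#' `elsewhere_in_genome` (`family_b` present but never co-operonic with
#' `family_a`), or `absent` (no `family_b`). Genomes containing any family in
#' `exclude` anywhere are dropped before counting - the bookkeeping used for
#' statements like "acr3 is in the same operon as arsA, but arsB and arsP are
#' nowhere in the genome".
#'
#' @param features Feature data.frame covering one or more genomes.
#' @param family_a,family_b Family labels.
#' @param exclude Optional character vector of family labels that disqualify a
#'   genome.
#' @param max_gap,require_same_strand Passed to [call_operons()].
#' @return List of class `"association_profile"`: counts `n_same_operon`,
#'   `n_elsewhere_in_genome`, `n_absent`, and `per_genome` data.frame.
#' @export
association_profile <- function(features, family_a, family_b,
                                exclude = character(0), max_gap = 200L,
                                require_same_strand = TRUE) {
  d <- validate_features(features)
  ops <- call_operons(d, max_gap, require_same_strand)
  fam_by_genome <- split(d$family, d$genome)
  gen_a <- names(fam_by_genome)[vapply(fam_by_genome, function(f)
    family_a %in% f, logical(1))]
  if (length(gen_a) == 0L)
    warning("family_a '", family_a, "' absent from all genomes")
  if (length(exclude)) {
    drop <- vapply(fam_by_genome[gen_a], function(f)
      any(exclude %in% f), logical(1))
    gen_a <- gen_a[!drop]
  }
  opfam <- operon_families(ops)
  co_op <- ops$genome[vapply(opfam, function(f)
    family_a %in% f && family_b %in% f, logical(1))]
  cls <- vapply(gen_a, function(g) {
    if (g %in% co_op) "same_operon"
    else if (family_b %in% fam_by_genome[[g]]) "elsewhere_in_genome"
    else "absent"
  }, character(1))
  per_genome <- data.frame(genome = gen_a, class = unname(cls),
                           stringsAsFactors = FALSE)
  structure(list(family_a = family_a, family_b = family_b, exclude = exclude,
                 n_same_operon = sum(cls == "same_operon"),
                 n_elsewhere_in_genome = sum(cls == "elsewhere_in_genome"),
                 n_absent = sum(cls == "absent"),
                 per_genome = per_genome),
            class = "association_profile")
}

#' @export
print.association_profile <- function(x, ...) {
  cat(sprintf("%s vs %s%s: same operon %d, elsewhere in genome %d, absent %d\n",
              x$family_a, x$family_b,
              if (length(x$exclude))
                paste0(" (excluding ", paste(x$exclude, collapse = ","), ")")
              else "",
              x$n_same_operon, x$n_elsewhere_in_genome, x$n_absent))
  invisible(x)
}

#' Leaf name in the organism/paralogue convention
#'
#' Display names follow `<organism code><organism digit>[-<paralogue digit>]`
#' with a terminal `E` ("elsewhere") marking partners encoded in the same
#' genome but not the same operon, e.g. `Aaa1-2` or `Aaa1-3E`.
#'
#' @param org_code Three-letter organism code.
#' @param org_index Digit distinguishing organisms sharing a code.
#' @param paralog_index Optional paralogue digit.
#' @param elsewhere Append `E` for a non-co-operonic partner.
#' @return Character name.
#' @export
context_leaf_name <- function(org_code, org_index = 1L, paralog_index = NA,
                              elsewhere = FALSE) {
  paste0(org_code, org_index,
         ifelse(is.na(paralog_index), "", paste0("-", paralog_index)),
         ifelse(elsewhere, "E", ""))
}

#' Operon-restricted leaf pairing between two families
#'
#' For every operon containing both families, emits one pair per
#' (family-A member, family-B member) combination in that operon. Leaf ids
#' are the locus ids of the paired genes. When an operon contributes several
#' combinations (paralogues), all are emitted with the shared `operon_id`;
#' resolve with [select_best_pairing()]. With one member of each family per
#' operon the result is directly a valid [leaf_pairing()].
#'
#' @inheritParams association_profile
#' @return Data.frame `leaf_a`, `leaf_b`, `operon_id` (a `leaf_pairing` when
#'   unambiguous; plain candidates table otherwise).
#' @export
operon_pairing <- function(features, family_a, family_b, max_gap = 200L,
                           require_same_strand = TRUE) {
  d <- validate_features(features)
  ops <- call_operons(d, max_gap, require_same_strand)
  opfam <- operon_families(ops)
  oploc <- operon_loci(ops)
  rows <- list()
  for (k in seq_len(nrow(ops))) {
    fa <- which(opfam[[k]] == family_a)
    fb <- which(opfam[[k]] == family_b)
    if (length(fa) && length(fb)) {
      combo <- expand.grid(a = fa, b = fb)
      rows[[length(rows) + 1L]] <- data.frame(
        leaf_a = oploc[[k]][combo$a], leaf_b = oploc[[k]][combo$b],
        operon_id = ops$operon_id[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(leaf_pairing(character(0), character(0)))
  cand <- do.call(rbind, rows)
  if (!anyDuplicated(cand$leaf_a) && !anyDuplicated(cand$leaf_b))
    return(leaf_pairing(cand$leaf_a, cand$leaf_b, cand$operon_id))
  cand
}
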