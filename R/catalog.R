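#' Load the ArsA homologue catalog
#'
#' Reads a tab-separated catalog of ArsA-family homologues. Each row describes
#' one protein: a short abbreviation (unique within the catalog), the source
#' organism, its length in amino acids, an organismal-type label (phylum or
#' proteobacterial class, e.g. `"Firmicutes"`, `"γ"`, `"Euryarchaeota"`),
#' an opaque accession (GI) string, and the phylogenetic cluster (1-18) the
#' protein falls into on the full-family tree. The packaged catalog of 212
#' homologues ships as `system.file("extdata", "arsa_table1.tsv",
#' package = "arsafam")` and is the default.
#'
#' @param path Path to a TSV file with header columns `abbrev`, `organism`,
#'   `size_aa`, `organism_type`, `gi`, `cluster_id`.
#' @return A data.frame with one row per homologue and the six columns above,
#'   `size_aa` and `cluster_id` integer.
#' @export
#' @examples
#' cat212 <- load_catalog()
#' nrow(cat212)  # 212
load_catalog <- function(path = system.file("extdata", "arsa_table1.tsv",
                                            package = "arsafam")) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  req <- c("abbrev", "organism", "size_aa", "organism_type", "gi", "cluster_id")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("catalog is missing required field(s): ", paste(miss, collapse = ", "))
  d <- d[, req]
  if (nrow(d) == 0L) return(d_int(d))
  size <- suppressWarnings(as.integer(d$size_aa))
  cl <- suppressWarnings(as.integer(d$cluster_id))
  bad <- which(is.na(size) | size < 1L)
  if (length(bad))
    stop("row ", bad[1L], " (", d$abbrev[bad[1L]], "): size_aa is not a ",
         "positive integer: '", d$size_aa[bad[1L]], "'")
  bad <- which(is.na(cl) | cl < 1L | cl > 18L)
  if (length(bad))
    stop("row ", bad[1L], " (", d$abbrev[bad[1L]], "): cluster_id must be an ",
         "integer in 1..18, got '", d$cluster_id[bad[1L]], "'")
  bad <- which(!nzchar(d$abbrev) | duplicated(d$abbrev))
  if (length(bad))
    stop("row ", bad[1L], ": abbrev missing or duplicated: '",
         d$abbrev[bad[1L]], "'")
  d$size_aa <- size
  d$cluster_id <- cl
  d
}

d_int <- function(d) {
  d$size_aa <- integer(0)
  d$cluster_id <- integer(0)
  d
}

#' Round half away from zero to an integer
#'
#' Mean protein sizes are reported as integers with halves rounded up
#' (360.5 -> 361), unlike R's banker's rounding.
#' @param x numeric
#' @return integer-valued numeric
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Summarize one phylogenetic cluster of the catalog
#'
#' @param records Catalog data.frame as returned by [load_catalog()].
#' @param cluster_id Integer cluster id in 1..18.
#' @return A one-row data.frame: `cluster_id`, `n_members`, `mean_size_aa`
#'   (arithmetic mean rounded half-up), `max_size_aa`, and
#'   `domain_architecture` (`"single"` or `"double"`).
#' @export
#' @examples
#' summarize_cluster(load_catalog(), 2)  # 7 members, mean 337 aa
summarize_cluster <- function(records, cluster_id) {
  stopifnot(is.data.frame(records))
  cluster_id <- as.integer(cluster_id)
  sizes <- records$size_aa[records$cluster_id == cluster_id]
  if (length(sizes) == 0L)
    stop("no catalog records with cluster_id ", cluster_id)
  data.frame(
    cluster_id = cluster_id,
    n_members = length(sizes),
    mean_size_aa = as.integer(round_half_up(mean(sizes))),
    max_size_aa = max(sizes),
    domain_architecture = domain_architecture(cluster_id),
    stringsAsFactors = FALSE
  )
}

#' Summarize every cluster present in the catalog
#'
#' @inheritParams summarize_cluster
#' @return A data.frame with one row per cluster, ordered by cluster id.
#' @export
summarize_clusters <- function(records) {
  ids <- sort(unique(records$cluster_id))
  do.call(rbind, lapply(ids, function(i) summarize_cluster(records, i)))
}

#' Domain architecture of a phylogenetic cluster
#'
#' Clusters 1, 4, and 6 hold internally duplicated (double-domain) ATPases of
#' roughly 600 aa; all other clusters hold single-domain proteins of roughly
#' 300-400 aa.
#'
#' @param cluster_id Integer in 1..18.
#' @return `"double"` for clusters 1, 4, 6; `"single"` otherwise.
#' @export
domain_architecture <- function(cluster_id) {
  cluster_id <- as.integer(cluster_id)
  if (length(cluster_id) != 1L || is.na(cluster_id) ||
      cluster_id < 1L || cluster_id > 18L)
    stop("cluster_id must be a single integer in 1..18")
  if (cluster_id %in% c(1L, 4L, 6L)) "double" else "single"
}
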