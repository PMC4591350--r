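protein_kmers <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(x)
  unique(substring(x, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
}

# Global identity/coverage of a protein pair relative to the shorter
# sequence, from one Needleman-Wunsch alignment (BLOSUM62).
pair_identity <- function(a, b, submat) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = 10, gapExtension = 0.5)
  shorter <- min(nchar(a), nchar(b))
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & ps != "-"
  c(identity = sum(pa == ps & both) / shorter,
    coverage = sum(both) / shorter)
}

#' Cluster CDS proteins across genomes into ortholog clusters
#'
#' Builds single-linkage components of the graph whose edges are protein
#' pairs with global identity at least `min_identity` over at least
#' `min_coverage` of the shorter sequence. A shared-k-mer prefilter
#' limits the exact pairwise alignments to plausible pairs; every
#' surviving pair is aligned with Needleman-Wunsch (BLOSUM62). Cluster
#' ids are deterministic: each cluster is named after its
#' lexicographically smallest `genome:cds` member, so the result does
#' not depend on input order.
#'
#' @param proteins Data.frame with `genome_id`, `cds_id`, `protein`
#'   (amino-acid strings over the 20-letter alphabet plus `X`/`*`), e.g.
#'   from [cds_proteins()].
#' @param min_identity Identity threshold in `[0, 1]` (default 0.5).
#' @param min_coverage Coverage threshold in `[0, 1]` (default 0.5).
#' @param kmer Prefilter k-mer length (pairs sharing no k-mer are never
#'   aligned).
#' @return A list of `OrthologCluster`s, each a list with `cluster_id`
#'   and `members` (data.frame `genome_id`, `cds_id`), ordered by
#'   cluster id.
#' @export
cluster_cds <- function(proteins, min_identity = 0.5, min_coverage = 0.5,
                        kmer = 4L) {
  if (!nrow(proteins)) return(list())
  key <- paste(proteins$genome_id, proteins$cds_id, sep = ":")
  if (anyDuplicated(key)) stop_("duplicated genome:cds ids in input")
  n <- nrow(proteins)
  # shared-kmer candidate pairs
  km <- lapply(proteins$protein, protein_kmers, k = kmer)
  dt <- data.table::data.table(kmer = unlist(km),
                               idx = rep(seq_len(n), lengths(km)))
  cand <- dt[dt, on = "kmer", allow.cartesian = TRUE][idx < i.idx,
                                                      .(i = idx, j = i.idx)]
  cand <- unique(cand)
  submat <- get_blosum62()
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      st <- pair_identity(proteins$protein[cand$i[r]],
                          proteins$protein[cand$j[r]], submat)
      st["identity"] >= min_identity && st["coverage"] >= min_coverage
    }, logical(1))
    edges <- as.matrix(cand[keep, ])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(seq_len(n), comp), function(i) {
    mem <- proteins[i, c("genome_id", "cds_id")]
    mem <- mem[order(key[i]), , drop = FALSE]
    rownames(mem) <- NULL
    list(cluster_id = min(key[i]), members = mem)
  })
  unname(clusters[order(vapply(clusters, `[[`, character(1), "cluster_id"))])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Venn partition of ortholog clusters
#'
#' Assigns every cluster to the cell named by the set of genomes its
#' members come from; the cell holding all genomes is the core genome,
#' and singleton-genome cells are each genome's unique clusters. A
#' cluster with several CDS from one genome still occupies one cell.
#' Cell counts always sum to the number of clusters.
#'
#' @param clusters List of clusters from [cluster_cds()].
#' @param genome_ids All genome ids under comparison.
#' @return A list of class `VennPartition`: `genome_ids`, `cells`
#'   (named integer vector keyed by `+`-joined sorted genome subsets),
#'   `core` (count for the all-genomes cell), `n_clusters`.
#' @export
venn_partition <- function(clusters, genome_ids) {
  cells <- vapply(clusters, function(cl) {
    gs <- sort(unique(cl$members$genome_id))
    if (!all(gs %in% genome_ids))
      stop_("cluster %s contains genomes outside genome_ids", cl$cluster_id)
    paste(gs, collapse = "+")
  }, character(1))
  counts <- table(cells)
  cells_vec <- setNames(as.integer(counts), names(counts))
  core_key <- paste(sort(genome_ids), collapse = "+")
  structure(list(genome_ids = genome_ids, cells = cells_vec,
                 core = if (core_key %in% names(cells_vec))
                   cells_vec[[core_key]] else 0L,
                 n_clusters = length(clusters)),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat(sprintf("Venn partition of %d clusters over %d genomes (core = %d)\n",
              x$n_clusters, length(x$genome_ids), x$core))
  print(x$cells)
  invisible(x)
}

#' Per-category annotation counts
#'
#' Tabulates CDS records by functional category label. Records with a
#' missing or empty category are excluded from both the counts and the
#' total.
#'
#' @param cds Data.frame with a `category` column (one label or `NA`
#'   per CDS).
#' @return A list with `counts` (named integer vector, sorted by
#'   category) and `total`.
#' @export
category_summary <- function(cds) {
  cat <- cds$category
  cat <- cat[!is.na(cat) & nzchar(cat)]
  counts <- table(cat)
  list(counts = setNames(as.integer(counts), names(counts)),
       total = sum(counts))
}

#' Read pathway definitions from TSV
#'
#' Dialect: `pathway_id<TAB>EC,EC,...`, one pathway per line; every
#' pathway must list at least one enzyme.
#'
#' @param path TSV path.
#' @return A named list of character vectors of EC codes.
#' @export
read_pathways_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop_("pathway TSV parse error at line %d: expected 2 columns", i)
    ecs <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    ecs <- ecs[nzchar(ecs)]
    if (!length(ecs)) stop_("pathway %s lists no enzymes (line %d)", f[1], i)
    out[[f[1]]] <- ecs
  }
  out
}

#' Pathway completeness against an annotated enzyme set
#'
#' For a genome's set of annotated EC codes, computes the share of
#' pathways with every required enzyme present (`fraction_complete`)
#' and the share missing at most one enzyme (`fraction_all_but_one`,
#' which includes the complete pathways, so it is never smaller).
#'
#' @param pathways Named list of character vectors of EC codes (at
#'   least one pathway, each non-empty), e.g. from
#'   [read_pathways_tsv()].
#' @param annotated_ecs Character vector of EC codes present in the
#'   genome annotation.
#' @return Named numeric vector `c(fraction_complete,
#'   fraction_all_but_one)`, both in `[0, 1]`.
#' @examples
#' pw <- list(p1 = c("1.1.1.1"), p2 = c("1.1.1.1", "2.2.2.2"))
#' pathway_completeness(pw, "1.1.1.1") # 0.5, 1.0
#' @export
pathway_completeness <- function(pathways, annotated_ecs) {
  if (!length(pathways)) stop_("pathway list must be non-empty")
  if (any(lengths(pathways) == 0)) stop_("every pathway needs >= 1 enzyme")
  missing_n <- vapply(pathways, function(ecs)
    sum(!unique(ecs) %in% annotated_ecs), integer(1))
  c(fraction_complete = mean(missing_n == 0L),
    fraction_all_but_one = mean(missing_n <= 1L))
}
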