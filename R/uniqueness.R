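#' @import IRanges
NULL

#' Region sets: sorted, disjoint, merged intervals on one genome
#'
#' A `RegionSet` is a data.frame of 0-based half-open intervals
#' (`replicon`, `start`, `end`) carrying the owning `genome_id` as an
#' attribute. The constructor sorts, merges overlapping *and touching*
#' intervals per replicon, so a stored set is always maximally merged.
#'
#' @param genome_id Genome id the regions live on.
#' @param regions Data.frame with `replicon`, `start`, `end`
#'   (0-based half-open).
#' @return A `RegionSet` data.frame.
#' @export
region_set <- function(genome_id, regions = NULL) {
  if (is.null(regions) || !nrow(regions)) {
    out <- data.frame(replicon = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    if (any(regions$end <= regions$start))
      stop_("regions must be non-empty half-open intervals")
    merged <- lapply(split(regions, regions$replicon), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      data.frame(replicon = d$replicon[1],
                 start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$replicon, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "genome_id") <- genome_id
  class(out) <- c("RegionSet", "data.frame")
  out
}

#' @rdname region_set
#' @param x A `RegionSet`.
#' @export
region_length <- function(x) if (nrow(x)) sum(x$end - x$start) else 0L

#' @rdname region_set
#' @param ... Unused.
#' @export
as.data.frame.RegionSet <- function(x, ...) {
  data.frame(replicon = as.character(x$replicon),
             start = x$start, end = x$end, stringsAsFactors = FALSE)
}

regions_to_irl <- function(x, replicons) {
  sapply(replicons, function(r) {
    d <- x[x$replicon == r, , drop = FALSE]
    IRanges::IRanges(d$start + 1L, d$end)
  }, simplify = FALSE)
}

#' Jaccard index between two region sets
#'
#' Base-level intersection over union across all replicons; 1 when both
#' sets are empty.
#'
#' @param a,b `RegionSet` objects on the same genome.
#' @return A number in `[0, 1]`.
#' @export
region_jaccard <- function(a, b) {
  reps <- union(unique(a$replicon), unique(b$replicon))
  if (!length(reps)) return(1)
  inter <- 0L; uni <- 0L
  ia <- regions_to_irl(a, reps); ib <- regions_to_irl(b, reps)
  for (r in reps) {
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia[[r]], ib[[r]])))
    uni <- uni + sum(IRanges::width(IRanges::union(ia[[r]], ib[[r]])))
  }
  if (uni == 0) 1 else inter / uni
}

#' Merged alignment coverage on a reference genome
#'
#' Union of the query intervals of all segments whose query side lies on
#' `g`: a base aligned by many segments counts once, so repeats cannot
#' inflate coverage. Coverage is strand-agnostic.
#'
#' @param seg Segment data.frame (already filtered as desired).
#' @param g The reference `Genome`.
#' @return A `RegionSet` on `g`.
#' @export
coverage_union <- function(seg, g) {
  seg <- seg[seg$qgenome == g$genome_id, , drop = FALSE]
  if (nrow(seg)) {
    unknown <- setdiff(unique(seg$qreplicon), names(g$seqs))
    if (length(unknown))
      stop_("segments reference unknown replicon(s): %s",
            paste(unknown, collapse = ", "))
    lens <- replicon_lengths(g)
    if (any(seg$qend > lens[seg$qreplicon]))
      stop_("segment query interval exceeds replicon length on %s", g$genome_id)
  }
  region_set(g$genome_id,
             data.frame(replicon = seg$qreplicon, start = seg$qstart,
                        end = seg$qend, stringsAsFactors = FALSE))
}

#' Pairwise similarity matrix of a genome set
#'
#' `value[i, j]` is the percent of genome `i`'s bases (chromosome plus
#' plasmids pooled) covered by the merged union of the filtered
#' alignment segments of `i` against `j`. The matrix is asymmetric in
#' general because the denominators differ; the diagonal is `NA`.
#'
#' @param seg Segment data.frame holding all pairwise segments
#'   (pre-filtered, conventionally at 300 bp).
#' @param genomes Named list of `Genome` objects; names fix the matrix
#'   order.
#' @return A numeric matrix of percentages in `[0, 100]` with `NA`
#'   diagonal.
#' @export
similarity_matrix <- function(seg, genomes) {
  ids <- names(genomes)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) {
    gl <- genome_length(genomes[[i]])
    if (gl == 0) stop_("genome %s has zero length", i)
    for (j in ids) {
      if (i == j) next
      sij <- seg[seg$qgenome == i & seg$tgenome == j, , drop = FALSE]
      cov <- coverage_union(sij, genomes[[i]])
      m[i, j] <- 100 * region_length(cov) / gl
    }
  }
  m
}

#' Unique regions of a reference genome
#'
#' Complement, within each replicon, of the union of the reference
#' genome's alignment coverage against *all* other genomes; complement
#' intervals strictly longer than `min_unique_len` are kept (a region of
#' exactly `min_unique_len` bp is discarded, matching the "longer than
#' 300 bp" rule, while the segment pre-filter keeps ">= 300 bp" — the
#' two thresholds are deliberately different).
#'
#' @param g The reference `Genome`.
#' @param seg Segment data.frame of the reference against every other
#'   genome (query side on `g`; pre-filtered at >= 300 bp).
#' @param min_unique_len Strict lower bound on unique-region length.
#' @return A `RegionSet` of unique regions.
#' @export
unique_regions <- function(g, seg, min_unique_len = 300) {
  cov <- coverage_union(seg[seg$tgenome != g$genome_id, , drop = FALSE], g)
  lens <- replicon_lengths(g)
  out <- list()
  for (r in names(lens)) {
    ir <- IRanges::IRanges(cov$start[cov$replicon == r] + 1L,
                           cov$end[cov$replicon == r])
    gaps <- IRanges::gaps(ir, start = 1L, end = lens[[r]])
    gaps <- gaps[IRanges::width(gaps) > min_unique_len]
    if (length(gaps))
      out[[r]] <- data.frame(replicon = r, start = IRanges::start(gaps) - 1L,
                             end = IRanges::end(gaps), stringsAsFactors = FALSE)
  }
  region_set(g$genome_id, if (length(out)) do.call(rbind, out))
}

#' Uniqueness report for one genome
#'
#' Summarizes a genome's unique regions against its CDS annotation:
#' total unique length, percent of the genome, number of regions, ORFs
#' falling in unique regions (a CDS is "in" when at least half of its
#' length overlaps the unique set), the percent of those ORFs annotated
#' as hypothetical proteins (case-insensitive substring match on the
#' product), and the percent of unique-region bases outside any CDS.
#'
#' @param unique A `RegionSet` of unique regions.
#' @param cds CDS data.frame (`replicon`, `start`, `end`, `product`,
#'   0-based half-open), e.g. from [read_cds_gff3()].
#' @param g The `Genome`.
#' @param min_overlap Fraction of CDS length that must overlap the
#'   unique set (default 0.5).
#' @return A one-row data.frame with `genome_id`, `unique_length_bp`,
#'   `unique_pct`, `n_unique_regions`, `orfs_in_unique`,
#'   `pct_hypothetical_orfs`, `pct_not_annotated`.
#' @export
uniqueness_report <- function(unique, cds, g, min_overlap = 0.5) {
  gl <- genome_length(g)
  if (gl == 0) stop_("genome %s has zero length", g$genome_id)
  ulen <- region_length(unique)
  reps <- names(g$seqs)
  if (nrow(cds) && any(cds$end > replicon_lengths(g)[cds$replicon]))
    stop_("CDS coordinates exceed replicon bounds")
  uirl <- regions_to_irl(unique, reps)
  orfs_in <- 0L; hypo_in <- 0L
  cds_cov_in_unique <- 0L
  for (r in reps) {
    ur <- uirl[[r]]
    d <- cds[cds$replicon == r, , drop = FALSE]
    if (nrow(d)) {
      cr <- IRanges::IRanges(d$start + 1L, d$end)
      ov <- IRanges::findOverlaps(cr, ur)
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          cr[S4Vectors::queryHits(ov)], ur[S4Vectors::subjectHits(ov)]))
        ov_per_cds <- tapply(w, S4Vectors::queryHits(ov), sum)
        idx <- as.integer(names(ov_per_cds))
        inside <- ov_per_cds >= min_overlap * IRanges::width(cr)[idx]
        orfs_in <- orfs_in + sum(inside)
        hypo_in <- hypo_in + sum(inside & grepl("hypothetical protein",
                                                d$product[idx],
                                                ignore.case = TRUE))
      }
      cds_cov_in_unique <- cds_cov_in_unique +
        sum(IRanges::width(IRanges::intersect(IRanges::reduce(cr), ur)))
    }
  }
  data.frame(
    genome_id = g$genome_id,
    unique_length_bp = ulen,
    unique_pct = if (ulen) 100 * ulen / gl else 0,
    n_unique_regions = nrow(unique),
    orfs_in_unique = orfs_in,
    pct_hypothetical_orfs = if (orfs_in) 100 * hypo_in / orfs_in else 0,
    pct_not_annotated = if (ulen) 100 * (ulen - cds_cov_in_unique) / ulen else 0,
    stringsAsFactors = FALSE)
}

#' Export a region set as BED
#'
#' BED uses the same 0-based half-open convention as the internal
#' representation, so coordinates pass through unchanged; names encode
#' `genome_id` and a running region index.
#'
#' @param x A `RegionSet`.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(x, path) {
  gid <- attr(x, "genome_id")
  write_atomic(path, function(tmp) {
    if (!nrow(x)) { file.create(tmp); return(invisible(NULL)) }
    bed <- data.frame(chrom = x$replicon, start = x$start, end = x$end,
                      name = sprintf("%s_unique_%04d", gid, seq_len(nrow(x))))
    utils::write.table(bed, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}
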