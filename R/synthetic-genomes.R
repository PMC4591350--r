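#' @import Biostrings
NULL

DNA_LETTERS <- c("A", "C", "G", "T")

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_LETTERS, n, replace = TRUE), collapse = "")
}

#' Construct a genome object
#'
#' A genome is a named set of replicon sequences (chromosome plus
#' plasmids). All coordinates elsewhere in the package are 0-based
#' half-open on these replicons; reports are converted to 1-based
#' inclusive at write time.
#'
#' @param genome_id Character id of the genome.
#' @param seqs A named [Biostrings::DNAStringSet] (names are replicon ids),
#'   or a named character vector of sequences.
#' @return An object of class `Genome`: a list with `genome_id` and `seqs`.
#' @export
genome <- function(genome_id, seqs) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_("replicon sequences must carry unique names")
  structure(list(genome_id = genome_id, seqs = seqs), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome %s: %d replicon(s), %s bp total\n", x$genome_id,
              length(x$seqs), format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' Total genome length and replicon lengths
#'
#' `genome_length()` pools all replicons (chromosome plus plasmids), the
#' denominator used by similarity scores and uniqueness percentages.
#'
#' @param g A `Genome` object.
#' @return `genome_length()`: a single integer; `replicon_lengths()`: a
#'   named integer vector.
#' @export
genome_length <- function(g) sum(Biostrings::width(g$seqs))

#' @rdname genome_length
#' @export
replicon_lengths <- function(g) {
  setNames(Biostrings::width(g$seqs), names(g$seqs))
}

#' Write genomes to FASTA
#'
#' Sequences are wrapped at 70 columns; record names are
#' `<genome_id>|<replicon_id>` so multi-genome files stay unambiguous.
#'
#' @param genomes A list of `Genome` objects (or a single one).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  seqs <- do.call(c, unname(lapply(genomes, function(g) {
    s <- g$seqs
    names(s) <- paste(g$genome_id, names(s), sep = "|")
    s
  })))
  write_atomic(path, function(tmp)
    Biostrings::writeXStringSet(seqs, tmp, width = 70))
}

#' Read genomes from a multi-replicon FASTA
#'
#' Inverse of [write_genome_fasta()]: record names `genome|replicon` are
#' split back into `Genome` objects; records without a `|` are treated as
#' replicons of a single genome named by `default_id`.
#'
#' @param path FASTA path.
#' @param default_id Genome id used for bare record names.
#' @return A named list of `Genome` objects.
#' @export
read_genome_fasta <- function(path, default_id = "genome") {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  has_bar <- grepl("|", nm, fixed = TRUE)
  gid <- ifelse(has_bar, sub("\\|.*$", "", nm), default_id)
  rid <- ifelse(has_bar, sub("^[^|]*\\|", "", nm), nm)
  out <- lapply(split(seq_along(seqs), gid), function(i) {
    s <- seqs[i]
    names(s) <- rid[i]
    genome(gid[i[1]], s)
  })
  out[unique(gid)]
}

# Compose gap lengths summing to at most `free` for `n` slots
# (stars-and-bars draw; all-zero when free == 0).
draw_gaps <- function(n, free) {
  if (free <= 0) return(rep(0L, n))
  cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
  diff(c(0L, cuts))
}

#' Simulate a set of genomes with planted shared and unique blocks
#'
#' Generates `n_genomes` multi-replicon genomes of i.i.d. uniform random
#' DNA into which shared blocks (verbatim copies present in the stated
#' member genomes) and unique blocks (present in exactly one genome) are
#' planted at recorded coordinates. The returned truth is the ground
#' truth for alignment-coverage and unique-region recovery tests.
#'
#' Blocks are placed first-fit into each genome's replicons in plan
#' order, separated by random gaps of background DNA; a plan whose
#' blocks exactly fill a replicon therefore gets zero gaps, which makes
#' the complement of the shared blocks equal the planted unique blocks
#' exactly. With `rearrange = TRUE` the block order is permuted and
#' shared blocks are reverse-complemented with probability 1/2,
#' independently per genome.
#'
#' @param n_genomes Number of genomes.
#' @param replicon_plan List (one element per genome, recycled if length
#'   one) of integer vectors of replicon lengths in bp.
#' @param shared_blocks `NULL` or a data.frame with columns `length` (bp)
#'   and `members` (comma-separated genome indices, e.g. `"1,2,3"`).
#' @param unique_blocks `NULL` or a data.frame with columns `length` and
#'   `owner` (genome index).
#' @param rearrange Permute/invert block placement per genome.
#' @param seed Integer seed; identical inputs and seed give
#'   byte-identical genomes.
#' @return A list with `genomes` (named list of `Genome`) and `truth`
#'   (named list per genome: data.frames `shared` and `unique` with
#'   0-based half-open coordinates, plus `seed`).
#' @examples
#' sim <- simulate_genome_set(2, list(c(20000L)),
#'   shared_blocks = data.frame(length = 5000, members = "1,2"),
#'   unique_blocks = data.frame(length = 2000, owner = 1:2), seed = 1)
#' sim$truth$g1$unique
#' @export
simulate_genome_set <- function(n_genomes, replicon_plan,
                                shared_blocks = NULL, unique_blocks = NULL,
                                rearrange = FALSE, seed) {
  if (length(replicon_plan) == 1L)
    replicon_plan <- rep(replicon_plan, n_genomes)
  if (length(replicon_plan) != n_genomes)
    stop_("replicon_plan must have one entry per genome")
  if (any(unlist(replicon_plan) <= 0)) stop_("replicon lengths must be positive")
  if (!is.null(shared_blocks) && any(shared_blocks$length <= 0))
    stop_("shared block lengths must be positive")
  if (!is.null(unique_blocks) && any(unique_blocks$length <= 0))
    stop_("unique block lengths must be positive")

  with_seed(seed, {
    n_sh <- if (is.null(shared_blocks)) 0L else nrow(shared_blocks)
    sh_members <- if (n_sh) lapply(strsplit(as.character(shared_blocks$members), ","),
                                   function(x) as.integer(trimws(x)))
    sh_seq <- if (n_sh) vapply(shared_blocks$length, random_dna, character(1))
    n_un <- if (is.null(unique_blocks)) 0L else nrow(unique_blocks)
    un_seq <- if (n_un) vapply(unique_blocks$length, random_dna, character(1))

    genomes <- list()
    truth <- list()
    for (g in seq_len(n_genomes)) {
      gid <- paste0("g", g)
      rlens <- as.integer(replicon_plan[[g]])
      # blocks destined for this genome, in plan order
      blk <- data.frame(kind = character(), id = integer(), length = integer(),
                        seq = character(), stringsAsFactors = FALSE)
      if (n_sh) for (i in seq_len(n_sh)) if (g %in% sh_members[[i]])
        blk <- rbind(blk, data.frame(kind = "shared", id = i,
                                     length = shared_blocks$length[i],
                                     seq = sh_seq[i]))
      if (n_un) for (j in seq_len(n_un)) if (unique_blocks$owner[j] == g)
        blk <- rbind(blk, data.frame(kind = "unique", id = j,
                                     length = unique_blocks$length[j],
                                     seq = un_seq[j]))
      strand <- rep("+", nrow(blk))
      if (rearrange && nrow(blk) > 1L) {
        ord <- sample.int(nrow(blk))
        blk <- blk[ord, , drop = FALSE]
        flip <- blk$kind == "shared" & runif(nrow(blk)) < 0.5
        blk$seq[flip] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAStringSet(blk$seq[flip])))
        strand <- ifelse(flip, "-", "+")
      }
      # first-fit assignment of blocks to replicons
      remaining <- rlens
      assign_r <- integer(nrow(blk))
      for (b in seq_len(nrow(blk))) {
        fit <- which(remaining >= blk$length[b])
        if (!length(fit))
          stop_("genome %s: block plan exceeds replicon capacity", gid)
        assign_r[b] <- fit[1]
        remaining[fit[1]] <- remaining[fit[1]] - blk$length[b]
      }
      seqs <- character(length(rlens))
      sh_rec <- un_rec <- list()
      for (r in seq_along(rlens)) {
        idx <- which(assign_r == r)
        gaps <- draw_gaps(length(idx) + 1L, rlens[r] - sum(blk$length[idx]))
        pos <- 0L
        parts <- character(0)
        for (kk in seq_along(idx)) {
          b <- idx[kk]
          parts <- c(parts, random_dna(gaps[kk]), blk$seq[b])
          pos <- pos + gaps[kk]
          rec <- data.frame(block_id = blk$id[b],
                            replicon = paste0("r", r),
                            start = pos, end = pos + blk$length[b],
                            strand = strand[b], stringsAsFactors = FALSE)
          if (blk$kind[b] == "shared") {
            rec$members <- paste(sh_members[[blk$id[b]]], collapse = ",")
            sh_rec[[length(sh_rec) + 1L]] <- rec
          } else un_rec[[length(un_rec) + 1L]] <- rec[setdiff(names(rec), "strand")]
          pos <- pos + blk$length[b]
        }
        tail_gap <- rlens[r] - pos
        parts <- c(parts, random_dna(tail_gap))
        seqs[r] <- paste(parts, collapse = "")
      }
      names(seqs) <- paste0("r", seq_along(rlens))
      genomes[[gid]] <- genome(gid, seqs)
      truth[[gid]] <- list(
        genome_id = gid,
        shared = if (length(sh_rec)) do.call(rbind, sh_rec) else
          data.frame(block_id = integer(), replicon = character(),
                     start = integer(), end = integer(), strand = character(),
                     members = character()),
        unique = if (length(un_rec)) do.call(rbind, un_rec) else
          data.frame(block_id = integer(), replicon = character(),
                     start = integer(), end = integer()),
        seed = as.integer(seed))
    }
    list(genomes = genomes, truth = truth)
  })
}

#' Simulate a CDS annotation for a genome
#'
#' Places non-overlapping CDS features on both strands of every replicon
#' at the requested density. Product strings are `"hypothetical protein"`
#' with probability `hypothetical_fraction`, otherwise a generic numbered
#' product; each CDS draws one functional category from
#' `category_weights` and, optionally, an EC number from `ec_pool`.
#'
#' @param g A `Genome` object.
#' @param mean_cds_len Mean CDS length in bp (lengths are drawn normal
#'   with 20% CV, floored at 90 bp and rounded to codon multiples).
#' @param density CDS per kb of replicon. Placement is by rejection
#'   sampling, so the coding occupancy `density * mean_cds_len / 1000`
#'   should stay below roughly 0.5; denser plans exhaust the retry
#'   budget and raise a placement error.
#' @param hypothetical_fraction Proportion in `[0, 1]` of CDS annotated
#'   as hypothetical proteins.
#' @param category_weights Named numeric vector of category sampling
#'   weights.
#' @param ec_pool Optional character vector of EC numbers assigned
#'   uniformly to non-hypothetical CDS.
#' @param seed Integer seed.
#' @param max_tries Placement retries per CDS before a placement error.
#' @return A data.frame of CDS records: `cds_id`, `replicon`, `start`,
#'   `end` (0-based half-open), `strand`, `product`, `category`, `ec`.
#' @export
simulate_cds_annotation <- function(g, mean_cds_len = 900, density = 0.8,
                                    hypothetical_fraction = 0.3,
                                    category_weights = c(Metabolism = 1),
                                    ec_pool = NULL, seed, max_tries = 200L) {
  if (hypothetical_fraction < 0 || hypothetical_fraction > 1)
    stop_("hypothetical_fraction must be in [0, 1]")
  if (density <= 0) stop_("density must be > 0")
  with_seed(seed, {
    recs <- list()
    n_done <- 0L
    for (r in names(g$seqs)) {
      L <- Biostrings::width(g$seqs[r])
      n <- max(0L, as.integer(round(density * L / 1000)))
      if (!n) next
      occupied <- IRanges::IRanges()
      for (i in seq_len(n)) {
        len <- max(90L, as.integer(round(rnorm(1, mean_cds_len, 0.2 * mean_cds_len))))
        len <- 3L * (len %/% 3L)
        if (len >= L) len <- 3L * ((L - 1L) %/% 3L)
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          s <- sample.int(L - len, 1L) - 1L  # 0-based start
          cand <- IRanges::IRanges(s + 1L, s + len)
          if (!length(IRanges::findOverlaps(cand, occupied))) {
            occupied <- c(occupied, cand)
            n_done <- n_done + 1L
            hypo <- runif(1) < hypothetical_fraction
            recs[[length(recs) + 1L]] <- data.frame(
              cds_id = sprintf("%s_cds%04d", g$genome_id, n_done),
              replicon = r, start = s, end = s + len,
              strand = sample(c("+", "-"), 1L),
              product = if (hypo) "hypothetical protein"
                        else sprintf("predicted protein %d", n_done),
              category = sample(names(category_weights), 1L,
                                prob = category_weights),
              ec = if (!hypo && !is.null(ec_pool)) sample(ec_pool, 1L)
                   else NA_character_,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop_("CDS placement failed on %s after %d tries (density too high)",
                r, max_tries)
      }
    }
    if (!length(recs))
      return(data.frame(cds_id = character(), replicon = character(),
                        start = integer(), end = integer(), strand = character(),
                        product = character(), category = character(),
                        ec = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Write and read CDS annotations as GFF3
#'
#' CDS records travel as GFF3 (1-based inclusive coordinates) with
#' `product=`, `category=` and `ec_number=` attributes, via
#' \pkg{rtracklayer}.
#'
#' @param cds A CDS data.frame as returned by [simulate_cds_annotation()].
#' @param path GFF3 path.
#' @param genome_id Genome id recorded in the `ID` attributes on write
#'   (defaults to ids already present in `cds_id`).
#' @return `write_cds_gff3()`: the path, invisibly; `read_cds_gff3()`: a
#'   CDS data.frame with 0-based half-open coordinates.
#' @export
write_cds_gff3 <- function(cds, path, genome_id = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = cds$replicon,
    ranges = IRanges::IRanges(cds$start + 1L, cds$end),
    strand = cds$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "panpheno"
  S4Vectors::mcols(gr)$ID <- cds$cds_id
  S4Vectors::mcols(gr)$product <- cds$product
  if (!is.null(cds$category)) S4Vectors::mcols(gr)$category <- cds$category
  if (!is.null(cds$ec)) S4Vectors::mcols(gr)$ec_number <- cds$ec
  write_atomic(path, function(tmp) rtracklayer::export(gr, tmp, format = "gff3"))
}

#' @rdname write_cds_gff3
#' @export
read_cds_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "CDS"]
  mc <- S4Vectors::mcols(gr)
  grab <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else NA_character_
  data.frame(
    cds_id = grab("ID"),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = grab("product"),
    category = grab("category"),
    ec = grab("ec_number"),
    stringsAsFactors = FALSE)
}

#' Extract and translate CDS protein sequences from a genome
#'
#' Pulls each CDS interval from its replicon (reverse-complementing
#' minus-strand features) and translates it, yielding the protein table
#' consumed by [cluster_cds()]. Internal stop codons in synthetic random
#' DNA are kept as `*` characters.
#'
#' @param g A `Genome` object.
#' @param cds A CDS data.frame for that genome.
#' @return A data.frame with `genome_id`, `cds_id`, `protein`.
#' @export
cds_proteins <- function(g, cds) {
  if (!nrow(cds))
    return(data.frame(genome_id = character(), cds_id = character(),
                      protein = character(), stringsAsFactors = FALSE))
  dna <- Biostrings::DNAStringSet(lapply(seq_len(nrow(cds)), function(i) {
    s <- Biostrings::subseq(g$seqs[[cds$replicon[i]]],
                            cds$start[i] + 1L, cds$end[i])
    if (cds$strand[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  prot <- Biostrings::translate(dna, if.fuzzy.codon = "X")
  data.frame(genome_id = g$genome_id, cds_id = cds$cds_id,
             protein = as.character(prot), stringsAsFactors = FALSE)
}
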