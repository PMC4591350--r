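SEGMENT_COLS <- c("qgenome", "qreplicon", "qstart", "qend",
                  "tgenome", "treplicon", "tstart", "tend",
                  "strand", "identity")

# Canonical empty segment table.
empty_segments <- function() {
  data.frame(qgenome = character(), qreplicon = character(),
             qstart = integer(), qend = integer(),
             tgenome = character(), treplicon = character(),
             tstart = integer(), tend = integer(),
             strand = character(), identity = numeric(),
             stringsAsFactors = FALSE)
}

validate_segments <- function(seg) {
  missing <- setdiff(setdiff(SEGMENT_COLS, "identity"), names(seg))
  if (length(missing))
    stop_("segment table lacks column(s): %s", paste(missing, collapse = ", "))
  if (!"identity" %in% names(seg)) seg$identity <- NA_real_
  bad <- which(seg$qstart < 0 | seg$qend <= seg$qstart |
               seg$tstart < 0 | seg$tend <= seg$tstart)
  if (length(bad))
    stop_("segment %d has an empty or negative interval", bad[1])
  if (!all(seg$strand %in% c("+", "-")))
    stop_("segment strand must be '+' or '-'")
  seg[, SEGMENT_COLS]
}

#' Read pairwise local-alignment segments
#'
#' Two dialects are supported. The TSV dialect is one row per segment
#' with columns `qgenome qreplicon qstart qend tgenome treplicon tstart
#' tend strand` (0-based half-open coordinates) plus an optional tenth
#' `identity` column. The MAF dialect (UCSC `a`/`s` lines, sequence
#' sources named `genome.replicon`) yields one segment per aligned pair
#' within each block; minus-strand MAF coordinates, which count from the
#' reverse-complement start, are converted to forward-strand half-open
#' intervals. When both sequence texts are present the column identity
#' of the block is recorded.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"maf"`.
#' @return A segment data.frame (possibly empty) with the ten canonical
#'   columns.
#' @export
read_segments <- function(path, format = c("tsv", "maf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("no such file: %s", path)
  if (format == "tsv") read_segments_tsv(path) else read_segments_maf(path)
}

read_segments_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_segments())
  if (startsWith(lines[1], "qgenome")) lines <- lines[-1]
  if (!length(lines)) return(empty_segments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 9L | n > 10L)
  if (length(bad))
    stop_("TSV segment parse error at line %d: expected 9 or 10 columns, got %d",
          bad[1], n[bad[1]])
  m <- t(vapply(fields, function(f) c(f, rep(NA_character_, 10L - length(f))),
                character(10)))
  num <- function(j, line_off = 0) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & !is.na(m[, j]))
    if (length(bad))
      stop_("TSV segment parse error at line %d: non-numeric field %d",
            bad[1], j)
    v
  }
  seg <- data.frame(qgenome = m[, 1], qreplicon = m[, 2],
                    qstart = num(3), qend = num(4),
                    tgenome = m[, 5], treplicon = m[, 6],
                    tstart = num(7), tend = num(8),
                    strand = m[, 9],
                    identity = suppressWarnings(as.numeric(m[, 10])),
                    stringsAsFactors = FALSE)
  validate_segments(seg)
}

# split "genome.replicon" at the first dot
split_src <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot < 0) c(src, src) else
    c(substr(src, 1, dot - 1), substr(src, dot + 1, nchar(src)))
}

read_segments_maf <- function(path) {
  lines <- readLines(path)
  segs <- list()
  block_s <- list()
  flush_block <- function() {
    if (length(block_s) >= 2L) {
      q <- block_s[[1]]
      for (i in 2:length(block_s)) {
        t <- block_s[[i]]
        ident <- if (nzchar(q$text) && nzchar(t$text)) {
          qc <- strsplit(q$text, "")[[1]]
          tc <- strsplit(t$text, "")[[1]]
          ok <- qc != "-" & tc != "-"
          if (any(ok)) mean(toupper(qc[ok]) == toupper(tc[ok])) else NA_real_
        } else NA_real_
        segs[[length(segs) + 1L]] <<- data.frame(
          qgenome = q$genome, qreplicon = q$replicon,
          qstart = q$fstart, qend = q$fend,
          tgenome = t$genome, treplicon = t$replicon,
          tstart = t$fstart, tend = t$fend,
          strand = if (q$strand == t$strand) "+" else "-",
          identity = ident, stringsAsFactors = FALSE)
      }
    }
    block_s <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) { flush_block(); next }
    if (startsWith(line, "a")) { flush_block(); next }
    if (!startsWith(line, "s ")) next
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) < 6L)
      stop_("MAF parse error at line %d: malformed 's' line", ln)
    start <- suppressWarnings(as.numeric(f[3]))
    size <- suppressWarnings(as.numeric(f[4]))
    src_size <- suppressWarnings(as.numeric(f[6]))
    if (anyNA(c(start, size, src_size)))
      stop_("MAF parse error at line %d: non-numeric coordinate", ln)
    if (start + size > src_size)
      stop_("MAF bounds error at line %d: start + size exceeds srcSize", ln)
    gr <- split_src(f[2])
    fstart <- if (f[5] == "-") src_size - start - size else start
    block_s[[length(block_s) + 1L]] <- list(
      genome = gr[1], replicon = gr[2], strand = f[5],
      fstart = fstart, fend = fstart + size,
      text = if (length(f) >= 7L) f[7] else "")
  }
  flush_block()
  if (!length(segs)) return(empty_segments())
  validate_segments(do.call(rbind, segs))
}

#' Write alignment segments
#'
#' Writes the canonical segment table either as the 10-column TSV
#' dialect or as MAF. MAF output emits one `a` block per segment with
#' two `s` lines; real sequence text is filled in when the `genomes`
#' the segments refer to are supplied (only gapless, equal-span
#' segments can be written to MAF), otherwise `N` runs stand in.
#'
#' @param seg Segment data.frame.
#' @param path Output file.
#' @param format `"tsv"` or `"maf"`.
#' @param genomes Optional named list of `Genome` objects keyed by
#'   genome id (for MAF sequence text and srcSize fields).
#' @param src_sizes Optional named vector of replicon lengths keyed
#'   `genome.replicon`, used for MAF `srcSize` when `genomes` is absent.
#' @return The path, invisibly.
#' @export
write_segments <- function(seg, path, format = c("tsv", "maf"),
                           genomes = NULL, src_sizes = NULL) {
  format <- match.arg(format)
  seg <- if (nrow(seg)) validate_segments(seg) else empty_segments()
  if (format == "tsv") {
    return(write_atomic(path, function(tmp)
      utils::write.table(seg, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)))
  }
  qlen <- seg$qend - seg$qstart
  tlen <- seg$tend - seg$tstart
  if (nrow(seg) && any(qlen != tlen))
    stop_("MAF output requires equal query/target spans (gapless segments)")
  size_of <- function(gid, rid) {
    if (!is.null(genomes) && gid %in% names(genomes))
      return(replicon_lengths(genomes[[gid]])[[rid]])
    key <- paste(gid, rid, sep = ".")
    if (!is.null(src_sizes) && key %in% names(src_sizes))
      return(src_sizes[[key]])
    NA_integer_
  }
  seq_of <- function(gid, rid, s, e, revcomp = FALSE) {
    if (!is.null(genomes) && gid %in% names(genomes)) {
      x <- Biostrings::subseq(genomes[[gid]]$seqs[[rid]], s + 1L, e)
      if (revcomp) x <- Biostrings::reverseComplement(x)
      return(as.character(x))
    }
    strrep("N", e - s)
  }
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("##maf version=1 scoring=none", con)
    for (i in seq_len(nrow(seg))) {
      qsz <- size_of(seg$qgenome[i], seg$qreplicon[i])
      tsz <- size_of(seg$tgenome[i], seg$treplicon[i])
      if (is.na(qsz)) qsz <- seg$qend[i]
      if (is.na(tsz)) tsz <- seg$tend[i]
      writeLines("a", con)
      writeLines(sprintf("s %s.%s %d %d + %d %s",
                         seg$qgenome[i], seg$qreplicon[i], seg$qstart[i],
                         qlen[i], qsz,
                         seq_of(seg$qgenome[i], seg$qreplicon[i],
                                seg$qstart[i], seg$qend[i])), con)
      if (seg$strand[i] == "+") {
        writeLines(sprintf("s %s.%s %d %d + %d %s",
                           seg$tgenome[i], seg$treplicon[i], seg$tstart[i],
                           tlen[i], tsz,
                           seq_of(seg$tgenome[i], seg$treplicon[i],
                                  seg$tstart[i], seg$tend[i])), con)
      } else {
        # minus strand: MAF start counts from the reverse-complement origin
        writeLines(sprintf("s %s.%s %d %d - %d %s",
                           seg$tgenome[i], seg$treplicon[i],
                           tsz - seg$tend[i], tlen[i], tsz,
                           seq_of(seg$tgenome[i], seg$treplicon[i],
                                  seg$tstart[i], seg$tend[i], revcomp = TRUE)),
                   con)
      }
      writeLines("", con)
    }
  })
}

#' Filter segments by minimum query length
#'
#' Keeps segments whose query interval spans at least `min_len` bp
#' (a 300 bp segment is kept, 299 bp is removed). This is the standard
#' pre-filter applied before similarity and uniqueness analyses.
#'
#' @param seg Segment data.frame.
#' @param min_len Minimum query span in bp (`>= 0`).
#' @return The filtered segment data.frame.
#' @export
filter_segments <- function(seg, min_len = 300) {
  if (min_len < 0) stop_("min_len must be >= 0")
  if (!nrow(seg)) return(seg)
  seg[seg$qend - seg$qstart >= min_len, , drop = FALSE]
}

# k-mer start positions excluding any window containing N
kmer_table <- function(seq_chr, k) {
  L <- nchar(seq_chr)
  if (L < k) return(data.table::data.table(kmer = character(), pos = integer()))
  starts <- seq_len(L - k + 1L)
  km <- substring(seq_chr, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", km)
  data.table::data.table(kmer = km[keep], pos = starts[keep] - 1L)  # 0-based
}

# Chain exact k-mer matches lying on one diagonal with query gaps
# <= max_gap; returns chains as (qstart, qend, tstart, tend), 0-based.
chain_diagonal <- function(qpos, tpos, k, max_gap) {
  o <- order(tpos - qpos, qpos)
  qpos <- qpos[o]; tpos <- tpos[o]
  diag <- tpos - qpos
  new_chain <- c(TRUE, diff(diag) != 0 | diff(qpos) - k > max_gap)
  id <- cumsum(new_chain)
  qs <- tapply(qpos, id, min)
  qe <- tapply(qpos, id, max) + k
  ts <- tapply(tpos, id, min)
  te <- tapply(tpos, id, max) + k
  data.frame(qstart = as.integer(qs), qend = as.integer(qe),
             tstart = as.integer(ts), tend = as.integer(te))
}

#' Desk-scale anchor aligner
#'
#' A deterministic stand-in for an external local aligner, sufficient
#' for synthetic genomes: exact k-mer matches on both strands are
#' chained when colinear (same diagonal) with query gaps of at most
#' `max_gap` bp, and chains spanning at least `min_chain` query bp are
#' emitted as gapless segments. `N` never matches. At `k = 15` the
#' expected number of spurious k-mer collisions between two independent
#' random 10-kb sequences is `2 * (10^4)^2 / 4^15` which is far below
#' one, so segments reflect genuinely shared sequence.
#'
#' @param genome_a,genome_b `Genome` objects (query and target).
#' @param k Seed k-mer length (`>= 8`).
#' @param max_gap Maximum query gap within a chain, bp.
#' @param min_chain Minimum query span of an emitted chain, bp.
#' @return A segment data.frame (query side on `genome_a`).
#' @export
anchor_align <- function(genome_a, genome_b, k = 15L, max_gap = 100L,
                         min_chain = 300L) {
  if (k < 8L) stop_("k must be >= 8")
  if (min(replicon_lengths(genome_a), replicon_lengths(genome_b)) < k)
    stop_("k exceeds the shortest replicon length")
  out <- list()
  for (qr in names(genome_a$seqs)) {
    qtab <- kmer_table(as.character(genome_a$seqs[[qr]]), k)
    if (!nrow(qtab)) next
    data.table::setkey(qtab, kmer)
    for (tr in names(genome_b$seqs)) {
      tseq <- genome_b$seqs[[tr]]
      tL <- length(tseq)  # DNAString length in bases
      for (strand in c("+", "-")) {
        s_chr <- if (strand == "+") as.character(tseq) else
          as.character(Biostrings::reverseComplement(tseq))
        ttab <- kmer_table(s_chr, k)
        if (!nrow(ttab)) next
        hits <- qtab[ttab, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
        if (!nrow(hits)) next
        ch <- chain_diagonal(hits$pos, hits$i.pos, k, max_gap)
        ch <- ch[ch$qend - ch$qstart >= min_chain, , drop = FALSE]
        if (!nrow(ch)) next
        if (strand == "-") {
          ts <- tL - ch$tend
          ch$tend <- tL - ch$tstart
          ch$tstart <- ts
        }
        out[[length(out) + 1L]] <- data.frame(
          qgenome = genome_a$genome_id, qreplicon = qr,
          qstart = ch$qstart, qend = ch$qend,
          tgenome = genome_b$genome_id, treplicon = tr,
          tstart = ch$tstart, tend = ch$tend,
          strand = strand, identity = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_segments())
  seg <- do.call(rbind, out)
  # deterministic order: leftmost query start first
  seg <- seg[order(seg$qreplicon, seg$qstart, seg$qend,
                   seg$treplicon, seg$tstart, seg$strand), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' All-vs-all anchor alignment of a genome set
#'
#' Runs [anchor_align()] for every ordered pair of distinct genomes and
#' binds the segments into one table, the input expected by
#' [similarity_matrix()] and [unique_regions()].
#'
#' @param genomes Named list of `Genome` objects.
#' @inheritParams anchor_align
#' @return A segment data.frame.
#' @export
anchor_align_all <- function(genomes, k = 15L, max_gap = 100L,
                             min_chain = 300L) {
  ids <- names(genomes)
  out <- list()
  for (a in ids) for (b in ids) if (a != b)
    out[[length(out) + 1L]] <- anchor_align(genomes[[a]], genomes[[b]],
                                            k = k, max_gap = max_gap,
                                            min_chain = min_chain)
  if (!length(out)) return(empty_segments())
  do.call(rbind, out)
}
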