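# Independent oracles and fixture builders shared across test files.

# Per-base boolean coverage oracle: mark [start, end) (0-based half-open)
# on a logical vector of replicon length.
bool_coverage <- function(len, starts, ends) {
  v <- logical(len)
  for (i in seq_along(starts)) if (ends[i] > starts[i])
    v[(starts[i] + 1L):ends[i]] <- TRUE
  v
}

# Runs of TRUE in a logical vector as 0-based half-open intervals.
bool_to_intervals <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# A genome of uniform 'A' sequence: interval algebra only, no alignment.
flat_genome <- function(id, lens) {
  seqs <- vapply(lens, function(L) strrep("A", L), character(1))
  names(seqs) <- paste0("r", seq_along(lens))
  genome(id, seqs)
}

# Segment rows on one genome pair with only the query side meaningful.
q_segments <- function(qgenome, qreplicon, starts, ends, tgenome = "other") {
  n <- length(starts)
  data.frame(qgenome = rep(qgenome, n), qreplicon = rep(qreplicon, n),
             qstart = starts, qend = ends,
             tgenome = rep(tgenome, n), treplicon = rep("r1", n),
             tstart = starts, tend = ends,
             strand = rep("+", n), identity = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

# Segments realizing a given permutation of target ranks: segment i on the
# query is matched to slot perm[i] on the target.
perm_segments <- function(perm) {
  n <- length(perm)
  data.frame(qgenome = rep("A", n), qreplicon = rep("r1", n),
             qstart = (seq_len(n) - 1L) * 1000L,
             qend = (seq_len(n) - 1L) * 1000L + 500L,
             tgenome = rep("B", n), treplicon = rep("r1", n),
             tstart = (perm - 1L) * 1000L,
             tend = (perm - 1L) * 1000L + 500L,
             strand = rep("+", n), identity = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

# Brute-force longest strictly increasing subsequence by enumeration
# (oracle for the synteny lis mode; n must stay small).
lis_brute <- function(x) {
  n <- length(x)
  best <- 0L
  for (m in seq_len(n)) {
    combos <- utils::combn(n, m)
    for (j in seq_len(ncol(combos))) {
      s <- x[combos[, j]]
      if (all(diff(s) > 0)) { best <- max(best, m); break }
    }
  }
  best
}

# Six-genome planted set whose blocks exactly tile each replicon: six
# 4-kb blocks shared by all genomes plus one 6-kb unique block per
# genome, so the complement of the shared backbone IS the planted
# unique region.
planted_six_genomes <- function(seed = 42) {
  simulate_genome_set(
    6, list(c(30000L)),
    shared_blocks = data.frame(length = rep(4000L, 6),
                               members = rep("1,2,3,4,5,6", 6)),
    unique_blocks = data.frame(length = rep(6000L, 6), owner = 1:6),
    seed = seed)
}

# Default PM grid used throughout the tests (15-min reads for 72 h).
pm_grid <- seq(0, 72, by = 0.25)

# Quadrature oracle for the baseline-subtracted area under a sigmoid.
quad_auc <- function(model, A, mu, lambda, y0, nu = 1) {
  stats::integrate(function(t)
    pmax(sigmoid_value(model, t, A, mu, lambda, y0, nu) - y0, 0),
    0, 72, subdivisions = 1000L, rel.tol = 1e-9)$value
}

# A plate spec with two planted strain-specific substrates among
# otherwise symmetric substrates.
planted_plate_spec <- function(n_shared = 10) {
  base <- list(model = "gompertz",
               s1 = c(A = 150, mu = 15, lambda = 5, y0 = 10),
               s2 = c(A = 150, mu = 15, lambda = 5, y0 = 10))
  spec <- rep(list(base), n_shared)
  names(spec) <- sprintf("shared%02d", seq_len(n_shared))
  spec$only_s1 <- list(model = "gompertz",
                       s1 = c(A = 220, mu = 20, lambda = 4, y0 = 10),
                       s2 = c(A = 0, mu = 0, lambda = 0, y0 = 10))
  spec$only_s2 <- list(model = "gompertz",
                       s1 = c(A = 0, mu = 0, lambda = 0, y0 = 10),
                       s2 = c(A = 220, mu = 20, lambda = 4, y0 = 10))
  spec
}
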