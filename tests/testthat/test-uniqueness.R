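test_that("coverage union merges overlapping segments", {
  g <- flat_genome("gA", 10000L)
  cov <- coverage_union(q_segments("gA", "r1", c(0L, 3500L), c(4000L, 6000L)), g)
  expect_equal(as.data.frame(cov),
               data.frame(replicon = "r1", start = 0L, end = 6000L))
  expect_equal(region_length(cov), 6000L)
  expect_equal(nrow(coverage_union(q_segments("gA", "r1", integer(0),
                                              integer(0)), g)), 0L)
  expect_error(coverage_union(q_segments("gA", "rX", 0L, 10L), g),
               "unknown replicon")
})

test_that("interval operations agree with the per-base boolean oracle", {
  set.seed(202)
  for (trial in 1:8) {
    L <- sample(2000:100000, 1)
    g <- flat_genome("gA", L)
    n <- sample(1:60, 1)
    starts <- sample.int(L, n) - 1L
    ends <- pmin(starts + sample.int(2000, n), L)
    keep <- ends > starts
    seg <- q_segments("gA", "r1", starts[keep], ends[keep], tgenome = "gB")

    v <- bool_coverage(L, starts[keep], ends[keep])
    cov <- coverage_union(seg, g)
    expect_identical(as.data.frame(cov)[c("start", "end")],
                     bool_to_intervals(v))
    expect_identical(region_length(cov), sum(v))

    # complement without a length filter conserves every base
    u0 <- unique_regions(g, seg, min_unique_len = 0)
    expect_identical(as.data.frame(u0)[c("start", "end")],
                     bool_to_intervals(!v))
    expect_identical(region_length(cov) + region_length(u0), L)

    # strict > 300 bp uniqueness filter against the oracle
    u300 <- unique_regions(g, seg, min_unique_len = 300)
    orc <- bool_to_intervals(!v)
    orc <- orc[orc$end - orc$start > 300, , drop = FALSE]
    rownames(orc) <- NULL
    expect_identical(as.data.frame(u300)[c("start", "end")], orc)
  }
})

test_that("similarity percentages follow covered bases over genome length", {
  g <- flat_genome("gA", 10000L)
  h <- flat_genome("gB", 10000L)
  seg <- rbind(q_segments("gA", "r1", c(0L, 3500L), c(4000L, 6000L),
                          tgenome = "gB"),
               q_segments("gB", "r1", 0L, 10000L, tgenome = "gA"))
  m <- similarity_matrix(seg, list(gA = g, gB = h))
  expect_equal(m["gA", "gB"], 60)
  expect_equal(m["gB", "gA"], 100)
  expect_true(is.na(m["gA", "gA"]))
  expect_error(similarity_matrix(seg, list(gA = g, gB = flat_genome("gB", 0L))),
               "zero length")
})

test_that("self-alignment gives 100.00 similarity", {
  set.seed(77)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  gA <- genome("gA", c(r1 = s))
  gB <- genome("gB", c(r1 = s))
  seg <- filter_segments(anchor_align_all(list(gA = gA, gB = gB)), 300)
  m <- similarity_matrix(seg, list(gA = gA, gB = gB))
  expect_equal(unname(m["gA", "gB"]), 100)
})

test_that("uniqueness drops gaps at or below the strict threshold", {
  g <- flat_genome("gA", 10000L)
  # coverage [0,4000) U [4200,9900): gaps of 200, 100 both rejected,
  # even the trailing 100 bp
  seg <- q_segments("gA", "r1", c(0L, 4200L), c(4000L, 9900L), tgenome = "gB")
  expect_equal(nrow(unique_regions(g, seg, 300)), 0L)
  # an exactly-300 complement interval is rejected ("longer than 300 bp")
  seg2 <- q_segments("gA", "r1", 300L, 10000L, tgenome = "gB")
  expect_equal(nrow(unique_regions(g, seg2, 300)), 0L)
  seg3 <- q_segments("gA", "r1", 301L, 10000L, tgenome = "gB")
  expect_equal(region_length(unique_regions(g, seg3, 300)), 301L)
  # no alignments at all: each replicon is one unique region
  g2 <- flat_genome("gB", c(5000L, 200L))
  u <- unique_regions(g2, q_segments("gB", "r1", integer(0), integer(0)), 300)
  expect_equal(as.data.frame(u),
               data.frame(replicon = "r1", start = 0L, end = 5000L))
})

test_that("adding a genome to the comparison never increases uniqueness", {
  sim <- simulate_genome_set(
    3, list(c(40000L)),
    shared_blocks = data.frame(length = c(5000L, 5000L, 4000L),
                               members = c("1,2", "1,3", "1,2,3")),
    seed = 13)
  g1 <- sim$genomes$g1
  seg12 <- filter_segments(anchor_align(g1, sim$genomes$g2), 300)
  seg13 <- filter_segments(anchor_align(g1, sim$genomes$g3), 300)
  u_two <- unique_regions(g1, seg12)
  u_three <- unique_regions(g1, rbind(seg12, seg13))
  expect_lte(region_length(u_three), region_length(u_two))
})

test_that("planted unique regions are recovered with Jaccard >= 0.95", {
  sim <- planted_six_genomes(seed = 42)
  seg <- filter_segments(anchor_align_all(sim$genomes), 300)
  jac <- vapply(names(sim$genomes), function(i) {
    rec <- unique_regions(sim$genomes[[i]],
                          seg[seg$qgenome == i, , drop = FALSE])
    truth <- region_set(i, sim$truth[[i]]$unique)
    region_jaccard(rec, truth)
  }, numeric(1))
  expect_true(all(jac >= 0.95))
})

test_that("uniqueness report counts ORFs, hypotheticals and bare bases", {
  g <- flat_genome("gA", 10000L)
  u <- region_set("gA", data.frame(replicon = "r1", start = 1000L,
                                   end = 2000L))
  # one hypothetical CDS fully inside the unique region
  cds <- data.frame(cds_id = "c1", replicon = "r1", start = 1000L,
                    end = 2000L, strand = "+",
                    product = "Hypothetical Protein", category = NA,
                    ec = NA, stringsAsFactors = FALSE)
  rep <- uniqueness_report(u, cds, g)
  expect_equal(rep$orfs_in_unique, 1L)
  expect_equal(rep$pct_hypothetical_orfs, 100)
  expect_equal(rep$pct_not_annotated, 0)
  expect_equal(rep$unique_pct, 10)

  # empty unique set: zero counts by convention
  rep0 <- uniqueness_report(region_set("gA"), cds, g)
  expect_equal(rep0$unique_length_bp, 0L)
  expect_equal(rep0$pct_hypothetical_orfs, 0)
  expect_equal(rep0$pct_not_annotated, 0)

  # membership needs >= 50% of the CDS length inside the unique set
  cds2 <- data.frame(cds_id = c("in", "out"), replicon = "r1",
                     start = c(1600L, 1900L), end = c(2400L, 3000L),
                     strand = "+", product = "p", category = NA, ec = NA,
                     stringsAsFactors = FALSE)
  rep2 <- uniqueness_report(u, cds2, g)
  expect_equal(rep2$orfs_in_unique, 1L)  # 400/800 in, 100/1100 out
})

test_that("report fields match direct enumeration on planted truth", {
  sim <- planted_six_genomes(seed = 5)
  g <- sim$genomes$g1
  u <- region_set("g1", sim$truth$g1$unique)
  cds <- simulate_cds_annotation(g, mean_cds_len = 600, density = 0.5,
                                 hypothetical_fraction = 0.4, seed = 8)
  rep <- uniqueness_report(u, cds, g)
  # enumeration oracle over the CDS table
  ulen <- region_length(u)
  ov <- vapply(seq_len(nrow(cds)), function(i) {
    span <- intersect(seq.int(cds$start[i] + 1L, cds$end[i]),
                      seq.int(u$start[1] + 1L, u$end[1]))
    length(span) >= 0.5 * (cds$end[i] - cds$start[i])
  }, logical(1))
  expect_equal(rep$orfs_in_unique, sum(ov))
  if (sum(ov)) {
    expect_equal(rep$pct_hypothetical_orfs,
                 100 * mean(cds$product[ov] == "hypothetical protein"))
  }
  v <- bool_coverage(replicon_lengths(g)[["r1"]],
                     cds$start[cds$replicon == "r1"],
                     cds$end[cds$replicon == "r1"])
  covered <- sum(v[(u$start[1] + 1L):u$end[1]])
  expect_equal(rep$pct_not_annotated, 100 * (ulen - covered) / ulen)
})
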