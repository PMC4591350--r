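test_that("planted blocks are recorded and copied verbatim", {
  sim <- simulate_genome_set(
    2, list(c(20000L)),
    shared_blocks = data.frame(length = 5000L, members = "1,2"),
    unique_blocks = data.frame(length = 2000L, owner = 1:2),
    seed = 1)
  expect_named(sim$genomes, c("g1", "g2"))
  for (g in c("g1", "g2")) {
    expect_equal(nrow(sim$truth[[g]]$shared), 1L)
    expect_equal(nrow(sim$truth[[g]]$unique), 1L)
  }
  # shared block is an exact substring copy in both genomes
  blk <- lapply(c("g1", "g2"), function(g) {
    tr <- sim$truth[[g]]$shared
    as.character(Biostrings::subseq(sim$genomes[[g]]$seqs[[tr$replicon]],
                                    tr$start + 1L, tr$end))
  })
  expect_identical(blk[[1]], blk[[2]])
  # planted shared and unique regions are disjoint within each genome
  tr <- sim$truth$g1
  iv <- rbind(tr$shared[c("start", "end")], tr$unique[c("start", "end")])
  iv <- iv[order(iv$start), ]
  expect_true(all(diff(as.vector(t(iv))) >= 0))
})

test_that("genome simulation is byte-identical under a fixed seed", {
  call_once <- function() {
    sim <- simulate_genome_set(
      2, list(c(8000L, 3000L)),
      shared_blocks = data.frame(length = c(1500L, 1200L),
                                 members = c("1,2", "1,2")),
      rearrange = TRUE, seed = 7)
    f <- tempfile(fileext = ".fa")
    write_genome_fasta(sim$genomes, f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(call_once(), call_once())
})

test_that("rearrangement shuffles the per-genome order of shared blocks", {
  sim <- simulate_genome_set(
    3, list(c(60000L)),
    shared_blocks = data.frame(length = rep(2000L, 20),
                               members = rep("1,2,3", 20)),
    rearrange = TRUE, seed = 11)
  ranks <- lapply(sim$truth, function(tr) {
    d <- tr$shared[order(tr$shared$start), ]
    d$block_id
  })
  # at least one genome pair orders the 20 blocks differently
  expect_false(identical(ranks[[1]], ranks[[2]]) &&
               identical(ranks[[2]], ranks[[3]]))
})

test_that("block plans exceeding replicon capacity fail loudly", {
  expect_error(
    simulate_genome_set(1, list(c(1000L)),
                        shared_blocks = data.frame(length = 2000L,
                                                   members = "1"),
                        seed = 1),
    "capacity")
})

test_that("hypothetical-protein fraction follows the requested rate", {
  g <- flat_genome("gx", 2000000L)
  none <- simulate_cds_annotation(g, density = 0.1,
                                  hypothetical_fraction = 0, seed = 3)
  expect_false(any(grepl("hypothetical", none$product)))

  cds <- simulate_cds_annotation(g, mean_cds_len = 600, density = 0.6,
                                 hypothetical_fraction = 0.4, seed = 3)
  expect_gte(nrow(cds), 900)
  n <- nrow(cds)
  obs <- sum(cds$product == "hypothetical protein")
  # analytic binomial 99% interval for p = 0.4
  expect_gte(obs, qbinom(0.005, n, 0.4))
  expect_lte(obs, qbinom(0.995, n, 0.4))
  # CDSs never overlap within a replicon
  d <- cds[order(cds$replicon, cds$start), ]
  expect_true(all(tapply(seq_len(nrow(d)), d$replicon, function(i)
    all(d$start[i][-1] >= head(d$end[i], -1)))))
})

test_that("degenerate category weights put every CDS in one category", {
  g <- flat_genome("gx", 50000L)
  cds <- simulate_cds_annotation(g, mean_cds_len = 400, density = 0.8,
                                 category_weights = c(OnlyOne = 1), seed = 5)
  cs <- category_summary(cds)
  expect_identical(names(cs$counts), "OnlyOne")
  expect_identical(cs$total, nrow(cds))
})

test_that("simulated curves match the closed forms", {
  # gompertz value at t = lambda is A * exp(-e) above baseline
  kc <- simulate_pm_curve("gompertz", c(A = 100, mu = 10, lambda = 5, y0 = 0),
                          noise_sd = 0, seed = 1)
  expect_equal(kc$signals[kc$times == 5], 100 * exp(-exp(1)), tolerance = 1e-12)
  expect_length(kc$times, 289L)

  # zero amplitude degenerates to the constant baseline for every model
  for (m in c("logistic", "gompertz", "richards")) {
    kc0 <- simulate_pm_curve(m, c(A = 0, mu = 5, lambda = 2, y0 = 7),
                             noise_sd = 0, seed = 1)
    expect_true(all(kc0$signals == 7))
  }

  # t -> infinity limit is y0 + A for all three models
  for (m in c("logistic", "gompertz", "richards"))
    expect_equal(sigmoid_value(m, 1e6, A = 80, mu = 10, lambda = 3, y0 = 5,
                               nu = 2), 85, tolerance = 1e-9)

  # noiseless grids equal the closed form to floating tolerance
  t <- pm_grid
  for (m in c("logistic", "gompertz", "richards")) {
    kc <- simulate_pm_curve(m, c(A = 120, mu = 12, lambda = 6, y0 = 3, nu = 2),
                            noise_sd = 0, seed = 9)
    expect_equal(kc$signals,
                 pmax(sigmoid_value(m, t, 120, 12, 6, 3, nu = 2), 0),
                 tolerance = 1e-9)
  }

  expect_error(simulate_pm_curve("gompertz", c(A = -1, mu = 1, lambda = 1,
                                               y0 = 0), seed = 1), "A")
  expect_error(simulate_pm_curve("gompertz", c(A = 1, mu = 1, lambda = 1,
                                               y0 = 0), noise_sd = -1,
                                 seed = 1), "noise_sd")
})

test_that("plate simulation labels specificity from noiseless AUC", {
  spec <- list(
    same = list(model = "gompertz",
                s1 = c(A = 100, mu = 10, lambda = 5, y0 = 0),
                s2 = c(A = 100, mu = 10, lambda = 5, y0 = 0)),
    only1 = list(model = "gompertz",
                 s1 = c(A = 200, mu = 20, lambda = 5, y0 = 0),
                 s2 = c(A = 0, mu = 0, lambda = 0, y0 = 0)))
  pl <- simulate_pm_plate(c("s1", "s2"), spec, noise_sd = 0, seed = 11)
  expect_identical(unname(pl$truth$specific_for["same"]), "none")
  expect_identical(unname(pl$truth$specific_for["only1"]), "s1")
  # one curve per strain x substrate x replicate
  expect_length(pl$curves, 2 * 2 * 2)
  # seeded determinism
  pl2 <- simulate_pm_plate(c("s1", "s2"), spec, noise_sd = 0, seed = 11)
  expect_identical(lapply(pl$curves, `[[`, "signals"),
                   lapply(pl2$curves, `[[`, "signals"))
  expect_error(simulate_pm_plate(c("s1", "s2"),
                                 list(x = list(s1 = c(A = 1))), seed = 1),
               "lacks parameters")
})
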