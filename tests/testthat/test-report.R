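genomics_fixture <- function(seed = 3) {
  sim <- simulate_genome_set(
    2, list(c(25000L)),
    shared_blocks = data.frame(length = c(6000L, 4000L),
                               members = rep("1,2", 2)),
    unique_blocks = data.frame(length = rep(3000L, 2), owner = 1:2),
    seed = seed)
  cds <- lapply(sim$genomes, simulate_cds_annotation,
                mean_cds_len = 600, density = 0.4,
                hypothetical_fraction = 0.3,
                category_weights = c(Metabolism = 2, Transport = 1),
                ec_pool = c("1.1.1.1", "2.2.2.2", "3.3.3.3"), seed = seed)
  list(sim = sim, cds = cds)
}

test_that("the genomics track produces all report tables", {
  fx <- genomics_fixture()
  pw_file <- tempfile(fileext = ".tsv")
  writeLines(c("pwA\t1.1.1.1,2.2.2.2", "pwB\t9.9.9.9"), pw_file)
  out <- tempfile()
  res <- run_genomics(list(genomes = fx$sim$genomes, cds = fx$cds,
                           pathways_file = pw_file, output_dir = out))
  expect_setequal(
    setdiff(list.files(out), "genomics_manifest.json"),
    c("similarity_matrix.tsv", "unique_g1.bed", "unique_g2.bed",
      "uniqueness_report.tsv", "order_conservation.tsv", "venn.json",
      "category_summary.tsv", "pathway_completeness.tsv"))
  expect_true(is.na(res$similarity["g1", "g1"]))
  expect_gt(res$similarity["g1", "g2"], 0)
  manifest <- jsonlite::read_json(file.path(out, "genomics_manifest.json"))
  expect_equal(manifest$stage, "genomics")
  expect_match(manifest$config_hash, "^[0-9a-f]{32}$")
  unlink(c(out, pw_file), recursive = TRUE)
})

test_that("re-running the genomics track is byte-identical", {
  fx <- genomics_fixture()
  read_all <- function() {
    out <- tempfile()
    run_genomics(list(genomes = fx$sim$genomes, cds = fx$cds,
                      output_dir = out))
    files <- sort(setdiff(list.files(out), "genomics_manifest.json"))
    content <- lapply(files, function(f) readLines(file.path(out, f)))
    unlink(out, recursive = TRUE)
    setNames(content, files)
  }
  expect_identical(read_all(), read_all())
})

test_that("uniqueness reported by the pipeline matches truth enumeration", {
  sim <- planted_six_genomes(seed = 9)
  out <- tempfile()
  res <- run_genomics(list(genomes = sim$genomes, output_dir = out))
  for (i in names(sim$genomes)) {
    truth_len <- sum(sim$truth[[i]]$unique$end - sim$truth[[i]]$unique$start)
    # anchor-chain edges can chance-extend by up to k-1 bp per boundary
    expect_lte(abs(region_length(res$unique[[i]]) - truth_len), 28L)
    expect_gte(region_jaccard(res$unique[[i]],
                              region_set(i, sim$truth[[i]]$unique)), 0.99)
  }
  unlink(out, recursive = TRUE)
})

test_that("the phenomics track writes activities, levels and delta tables", {
  spec <- planted_plate_spec(n_shared = 6)
  pl <- simulate_pm_plate(c("s1", "s2"), spec, noise_sd = 3, seed = 29)
  csv <- tempfile(fileext = ".csv"); man <- tempfile(fileext = ".tsv")
  write_kinetics(pl$curves, csv, man)
  out <- tempfile()
  res <- run_phenomics(list(
    kinetics_csv = csv, manifest_tsv = man,
    ec_mapping_file = system.file("extdata", "xenobiotic_ec_map.tsv",
                                  package = "panpheno"),
    output_dir = out))
  expect_setequal(
    setdiff(list.files(out), "phenomics_manifest.json"),
    c("curve_parameters.tsv", "activity_table.tsv", "heatmap.tsv",
      "delta_a.tsv", "scatter_table.tsv", "scatter_bands.tsv",
      "ec_association.tsv"))
  # one activity row per strain x plate x substrate
  expect_equal(nrow(res$activities), 2 * length(spec))
  expect_true(all(res$activities$level %in%
                  c("low", "lower-middle", "upper-middle", "high")))
  # planted specific substrates recovered end to end
  calls <- setNames(res$delta$table$call, res$delta$table$substrate)
  expect_identical(unname(calls["only_s1"]), "s1")
  expect_identical(unname(calls["only_s2"]), "s2")
  unlink(c(out, csv, man), recursive = TRUE)
})

test_that("a single-strain run skips the delta stage but keeps the rest", {
  kc <- lapply(1:2, function(i)
    simulate_pm_curve("gompertz", c(A = 100, mu = 10, lambda = 5, y0 = 5),
                      noise_sd = 1, seed = i, strain_id = "solo",
                      well_id = paste0("w", i), substrate = "glucose",
                      replicate = i))
  out <- tempfile()
  expect_message(
    res <- run_phenomics(list(curves = kc, output_dir = out)),
    "skipped")
  expect_null(res$delta)
  expect_true(file.exists(file.path(out, "activity_table.tsv")))
  expect_false(file.exists(file.path(out, "delta_a.tsv")))
  manifest <- jsonlite::read_json(file.path(out, "phenomics_manifest.json"))
  expect_true(any(grepl("skipped", unlist(manifest$warnings))))
  unlink(out, recursive = TRUE)
})

test_that("phenomics re-runs reproduce identical outputs", {
  spec <- planted_plate_spec(n_shared = 3)
  pl <- simulate_pm_plate(c("s1", "s2"), spec, noise_sd = 2, seed = 41)
  run_once <- function() {
    out <- tempfile()
    run_phenomics(list(curves = pl$curves, output_dir = out))
    files <- sort(setdiff(list.files(out), "phenomics_manifest.json"))
    content <- lapply(files, function(f) readLines(file.path(out, f)))
    unlink(out, recursive = TRUE)
    setNames(content, files)
  }
  expect_identical(run_once(), run_once())
})

test_that("config validation catches bad thresholds and missing inputs", {
  expect_error(run_genomics(list(min_segment_len = -1, output_dir = "x")),
               "non-negative")
  expect_error(run_genomics(list(output_dir = tempfile())),
               "genome")
  expect_error(run_phenomics(list(output_dir = tempfile())),
               "curves")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("min_segment_len: 500", "output_dir: /tmp/x"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$min_segment_len, 500)
  expect_equal(cfg$min_unique_len, 300)
  unlink(f)
})
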