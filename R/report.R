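#' Read a run configuration
#'
#' Configurations are plain YAML key-value files mirroring the
#' arguments of [run_genomics()] and [run_phenomics()]; see those
#' functions for the recognized keys. Thresholds must be positive and
#' genome ids unique.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("no such config file: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$min_segment_len <- cfg$min_segment_len %||% 300
  cfg$min_unique_len <- cfg$min_unique_len %||% 300
  cfg$synteny_mode <- cfg$synteny_mode %||% "strict_rank"
  cfg$min_identity <- cfg$min_identity %||% 0.5
  cfg$min_coverage <- cfg$min_coverage %||% 0.5
  cfg$cutpoints <- cfg$cutpoints %||% c(0.25, 0.5, 0.75)
  cfg$centering <- cfg$centering %||% "zero"
  cfg$seed <- cfg$seed %||% 1L
  if (cfg$min_segment_len < 0 || cfg$min_unique_len < 0)
    stop_("length thresholds must be non-negative")
  if (!is.null(cfg$genome_ids) && anyDuplicated(cfg$genome_ids))
    stop_("genome ids must be unique")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, stage, cfg, outputs, warnings) {
  manifest <- list(
    stage = stage,
    package = "panpheno",
    version = as.character(utils::packageVersion("panpheno")),
    config_hash = config_hash(cfg),
    outputs = outputs,
    warnings = warnings)
  write_atomic(file.path(out_dir, paste0(stage, "_manifest.json")),
               function(tmp) jsonlite::write_json(manifest, tmp,
                                                  auto_unbox = TRUE,
                                                  digits = NA))
}

load_config_genomes <- function(cfg) {
  if (!is.null(cfg$genomes)) return(cfg$genomes)  # in-memory Genome objects
  if (is.null(cfg$genome_fastas)) stop_("config lacks genomes/genome_fastas")
  missing <- cfg$genome_fastas[!file.exists(unlist(cfg$genome_fastas))]
  if (length(missing))
    stop_("missing genome FASTA: %s", paste(missing, collapse = ", "))
  genomes <- list()
  for (f in cfg$genome_fastas)
    for (g in read_genome_fasta(f)) {
      if (g$genome_id %in% names(genomes))
        stop_("genome id collision: %s", g$genome_id)
      genomes[[g$genome_id]] <- g
    }
  genomes
}

#' Run the genomics track end to end
#'
#' Orchestrates the alignment post-processing pipeline: obtain pairwise
#' segments (from an external TSV/MAF file named in the config, or from
#' the built-in [anchor_align_all()]), filter them, and write the
#' similarity matrix, per-genome unique-region BEDs, the uniqueness
#' report, the order-conservation matrix, the Venn partition of CDS
#' clusters, the per-category annotation summary, and (when a pathway
#' file is configured) the pathway-completeness table. Outputs are
#' written atomically; a manifest JSON records the config hash and any
#' warnings. Re-running with the same config and inputs reproduces the
#' outputs byte for byte.
#'
#' @param cfg Config list (or path to a YAML config): recognized keys
#'   are `genomes` (in-memory named list of `Genome`) or
#'   `genome_fastas`; `cds` (named list of CDS data.frames, optional)
#'   or `gff3s` (named list of GFF3 paths, optional); `segments_file` +
#'   `segments_format` (optional; default is the built-in aligner);
#'   `min_segment_len`, `min_unique_len` (defaults 300);
#'   `synteny_mode`; `min_identity`, `min_coverage` (clustering);
#'   `pathways_file` (optional); `output_dir`.
#' @return Invisibly, a list with the in-memory results (`similarity`,
#'   `unique`, `uniqueness`, `order`, `venn`, `categories`, `pathways`).
#' @export
run_genomics <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir %||% stop_("config lacks output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warns <- character(0)
  genomes <- load_config_genomes(cfg)
  ids <- names(genomes)
  log_msg("INFO", "genomics: %d genomes (%s)", length(ids),
          paste(ids, collapse = ", "))

  seg <- if (!is.null(cfg$segments_file)) {
    if (!file.exists(cfg$segments_file))
      stop_("missing segments file: %s", cfg$segments_file)
    read_segments(cfg$segments_file, cfg$segments_format %||% "tsv")
  } else {
    log_msg("INFO", "aligning all pairs with the built-in anchor aligner")
    anchor_align_all(genomes)
  }
  seg <- filter_segments(seg, cfg$min_segment_len)

  sim <- similarity_matrix(seg, genomes)
  write_tsv_atomic(data.frame(genome_id = rownames(sim),
                              round(sim, 2), check.names = FALSE),
                   file.path(out_dir, "similarity_matrix.tsv"))

  cds <- cfg$cds
  if (is.null(cds) && !is.null(cfg$gff3s))
    cds <- lapply(cfg$gff3s, read_cds_gff3)
  uniq <- list()
  rep_rows <- list()
  for (i in ids) {
    uniq[[i]] <- unique_regions(genomes[[i]], seg[seg$qgenome == i, ,
                                                  drop = FALSE],
                                cfg$min_unique_len)
    write_regions_bed(uniq[[i]], file.path(out_dir,
                                           sprintf("unique_%s.bed", i)))
    if (!is.null(cds[[i]]))
      rep_rows[[i]] <- uniqueness_report(uniq[[i]], cds[[i]], genomes[[i]])
  }
  uniq_report <- if (length(rep_rows)) do.call(rbind, rep_rows)
  if (!is.null(uniq_report))
    write_tsv_atomic(uniq_report, file.path(out_dir, "uniqueness_report.tsv"))
  else warns <- c(warns, "no CDS annotations: uniqueness report skipped")

  oc <- order_conservation_matrix(seg, ids, cfg$synteny_mode)
  write_tsv_atomic(data.frame(genome_id = rownames(oc), oc,
                              check.names = FALSE),
                   file.path(out_dir, "order_conservation.tsv"))

  venn <- NULL; cat_sum <- NULL
  if (!is.null(cds)) {
    prots <- do.call(rbind, lapply(ids, function(i)
      if (!is.null(cds[[i]])) cds_proteins(genomes[[i]], cds[[i]])))
    clusters <- cluster_cds(prots, cfg$min_identity, cfg$min_coverage)
    venn <- venn_partition(clusters, ids)
    write_atomic(file.path(out_dir, "venn.json"), function(tmp)
      jsonlite::write_json(list(genome_ids = venn$genome_ids,
                                cells = as.list(venn$cells),
                                core = venn$core,
                                n_clusters = venn$n_clusters),
                           tmp, auto_unbox = TRUE, digits = NA))
    cat_sum <- lapply(cds, category_summary)
    cat_df <- do.call(rbind, lapply(ids, function(i) {
      cs <- cat_sum[[i]]
      rbind(data.frame(genome_id = i, category = names(cs$counts),
                       n = cs$counts),
            data.frame(genome_id = i, category = "Total", n = cs$total))
    }))
    rownames(cat_df) <- NULL
    write_tsv_atomic(cat_df, file.path(out_dir, "category_summary.tsv"))
  } else warns <- c(warns, "no CDS annotations: Venn and categories skipped")

  pw <- NULL
  if (!is.null(cfg$pathways_file)) {
    pathways <- read_pathways_tsv(cfg$pathways_file)
    pw <- do.call(rbind, lapply(ids, function(i) {
      ecs <- if (!is.null(cds[[i]])) cds[[i]]$ec else character(0)
      ecs <- unique(ecs[!is.na(ecs)])
      pc <- pathway_completeness(pathways, ecs)
      data.frame(genome_id = i, fraction_complete = pc[["fraction_complete"]],
                 fraction_all_but_one = pc[["fraction_all_but_one"]])
    }))
    write_tsv_atomic(pw, file.path(out_dir, "pathway_completeness.tsv"))
  }

  write_manifest(out_dir, "genomics", cfg[!vapply(cfg, is.list, logical(1)) |
                                          names(cfg) %in% "cutpoints"],
                 list.files(out_dir), warns)
  invisible(list(similarity = sim, unique = uniq, uniqueness = uniq_report,
                 order = oc, venn = venn, categories = cat_sum,
                 pathways = pw, segments = seg))
}

#' Run the phenomics track end to end
#'
#' Reads a kinetics CSV plus manifest (or takes in-memory curves),
#' writes the per-well nine-parameter table, the activity table with
#' per-plate four-level categories and consistency flags, the
#' normalized heat-map matrix, and — when exactly two strains are
#' present — the activity-difference (delta A) table, the scatter-band
#' table and, if a mapping is configured, the EC association table.
#' With a single strain the delta stage is skipped with an explicit log
#' line. Inconsistent replicates are flagged, never dropped.
#'
#' @param cfg Config list (or YAML path): keys `curves` (in-memory list
#'   of `KineticCurve`) or `kinetics_csv` + `manifest_tsv`;
#'   `cutpoints`; `centering`; `consistency_tol` (default 0.25);
#'   `ec_mapping_file` (optional); `output_dir`.
#' @return Invisibly, a list with `parameters`, `activities`, `heatmap`,
#'   `delta` (NULL for one strain), `ec` (NULL without mapping).
#' @export
run_phenomics <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir %||% stop_("config lacks output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warns <- character(0)
  curves <- cfg$curves
  if (is.null(curves)) {
    if (is.null(cfg$kinetics_csv) || is.null(cfg$manifest_tsv))
      stop_("config lacks curves or kinetics_csv + manifest_tsv")
    curves <- withCallingHandlers(
      read_kinetics(cfg$kinetics_csv, cfg$manifest_tsv),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  log_msg("INFO", "phenomics: %d curves", length(curves))

  par_tab <- do.call(rbind, lapply(curves, function(kc)
    cbind(data.frame(strain_id = kc$strain_id, plate_id = kc$plate_id,
                     well_id = kc$well_id, substrate = kc$substrate,
                     replicate = kc$replicate, stringsAsFactors = FALSE),
          as.data.frame(as.list(curve_parameters(kc))))))
  write_tsv_atomic(par_tab, file.path(out_dir, "curve_parameters.tsv"))

  grp <- vapply(curves, function(kc)
    paste(kc$strain_id, kc$plate_id, kc$substrate, sep = "\r"), character(1))
  act <- do.call(rbind, lapply(split(curves, grp), activity,
                               consistency_tol = cfg$consistency_tol %||% 0.25))
  rownames(act) <- NULL
  act$level <- NA_character_
  act$heat <- NA_real_
  for (p in unique(act$plate_id)) {
    sel <- act$plate_id == p
    act$level[sel] <- as.character(categorize_activities(act$activity[sel],
                                                         cfg$cutpoints))
    act$heat[sel] <- normalize_heatmap(act$activity[sel])
  }
  write_tsv_atomic(act, file.path(out_dir, "activity_table.tsv"))
  heat <- act[, c("strain_id", "plate_id", "substrate", "heat")]
  write_tsv_atomic(heat, file.path(out_dir, "heatmap.tsv"))
  if (any(!act$consistent))
    warns <- c(warns, sprintf("%d inconsistent replicate set(s) flagged",
                              sum(!act$consistent)))

  strains <- sort(unique(act$strain_id))
  delta <- NULL; ec <- NULL
  if (length(strains) == 2L) {
    a_of <- function(st) {
      d <- act[act$strain_id == st, ]
      setNames(d$activity, d$substrate)[sort(unique(d$substrate))]
    }
    a1 <- a_of(strains[1]); a2 <- a_of(strains[2])
    shared <- intersect(names(a1), names(a2))
    delta <- delta_a_classify(a1[shared], a2[shared],
                              strain1 = strains[1], strain2 = strains[2],
                              centering = cfg$centering)
    dt <- delta$table
    dt$mu_a <- delta$mu_a
    dt$sigma_a <- delta$sigma_a
    write_tsv_atomic(dt, file.path(out_dir, "delta_a.tsv"))
    sc <- scatter_table(delta)
    write_tsv_atomic(sc$table, file.path(out_dir, "scatter_table.tsv"))
    write_tsv_atomic(data.frame(line = names(sc$offsets),
                                offset = unname(sc$offsets)),
                     file.path(out_dir, "scatter_bands.tsv"))
    if (!is.null(cfg$ec_mapping_file)) {
      ec <- ec_association(shared, read_ec_mapping(cfg$ec_mapping_file))
      write_tsv_atomic(ec[, c("substrate", "ec_codes")],
                       file.path(out_dir, "ec_association.tsv"))
    }
  } else {
    log_msg("INFO", "delta A stage skipped: %d strain(s) present",
            length(strains))
    warns <- c(warns, "delta A stage skipped (need exactly two strains)")
  }

  write_manifest(out_dir, "phenomics",
                 cfg[!vapply(cfg, is.list, logical(1)) |
                     names(cfg) %in% "cutpoints"],
                 list.files(out_dir), warns)
  invisible(list(parameters = par_tab, activities = act, heatmap = heat,
                 delta = delta, ec = ec))
}
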