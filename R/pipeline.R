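# Orchestration: simulate -> preprocess -> catalog -> subtract -> genotype
# -> reversals from one configuration, with serialized text intermediates
# so every stage is resumable and independently inspectable.

#' Build a pipeline configuration
#'
#' Merges user settings (a YAML file and/or a named list) over the package
#' defaults. Stage blocks: `sim` (see [sim_config()]), `preprocess`
#' (`tag_length`, `max_n_fraction`, `keep_residual`), `tagcat`
#' (`canonicalize`, `genome_size`), `subtract` (`source_sex`, `min_depth`,
#' `max_mismatch_fraction`, `seed_length`, `n_select`), `markers`
#' (`primer_length`, `size_tolerance_bp`), plus a global `rng_seed`.
#'
#' @param path Optional YAML file with (partial) stage blocks.
#' @param overrides Optional named list merged last.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  defaults <- list(
    rng_seed = 1L,
    sim = list(genome_length = 100000L, n_females = 4L, n_males = 4L,
               n_w_regions = 3L, w_region_length = 2000L,
               mean_depth = 5, error_rate = 0),
    preprocess = list(tag_length = 110L, max_n_fraction = 0.10,
                      keep_residual = TRUE),
    tagcat = list(canonicalize = TRUE, genome_size = 5e10),
    subtract = list(source_sex = "female", min_depth = 1L,
                    max_mismatch_fraction = 0.10, seed_length = 20L,
                    n_select = 100L),
    markers = list(primer_length = 20L, size_tolerance_bp = 5L)
  )
  cfg <- defaults
  merge_into <- function(base, extra) {
    for (k in names(extra)) {
      base[[k]] <- if (is.list(extra[[k]]) && is.list(base[[k]])) {
        merge_into(base[[k]], extra[[k]])
      } else {
        extra[[k]]
      }
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    cfg <- merge_into(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_into(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_paths <- function(out_dir) {
  list(
    male_fa = file.path(out_dir, "male_genome.fa"),
    female_fa = file.path(out_dir, "female_genome.fa"),
    truth = file.path(out_dir, "w_truth.tsv"),
    mids = file.path(out_dir, "mids.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    r1 = file.path(out_dir, "run_R1.fastq"),
    r2 = file.path(out_dir, "run_R2.fastq"),
    cleaned_dir = file.path(out_dir, "cleaned"),
    preprocess_summary = file.path(out_dir, "preprocess_summary.tsv"),
    catalog_dir = file.path(out_dir, "catalogs"),
    run_summary = file.path(out_dir, "run_summary.tsv"),
    screen = file.path(out_dir, "screen.tsv"),
    markers_fa = file.path(out_dir, "markers.fa"),
    markers_tsv = file.path(out_dir, "markers.tsv"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    reversals = file.path(out_dir, "reversals.tsv"),
    report = file.path(out_dir, "report.tsv"),
    manifest = file.path(out_dir, "MANIFEST.tsv")
  )
}

#' Run the full marker-discovery pipeline
#'
#' Runs simulate, preprocess, catalog, subtract, genotype and reversal
#' stages in order, serializing each stage's outputs as plain-text
#' FASTA/FASTQ/TSV under `out_dir`. A stage whose outputs already exist is
#' loaded rather than recomputed (delete files, or pass `force = TRUE`, to
#' redo); in particular, deleting only the final report and rerunning
#' regenerates it from intermediates. All TSV outputs carry the
#' configuration hash and seed in `#` comment headers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param force Recompute every stage even if outputs exist.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the final `report` data frame and the
#'   main intermediate objects.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(out_dir)
  hash <- rlang::hash(unclass(config))
  hdr <- c(config_hash = hash, rng_seed = config$rng_seed)
  note <- function(...) if (!quiet) message("[radsub] ", ...)
  done <- function(...) !force && all(file.exists(c(...)))

  scfg <- do.call(sim_config, c(config$sim, list(rng_seed = config$rng_seed)))
  residual <- substr(scfg$enzyme_a_site, scfg$enzyme_a_cut + 1L,
                     nchar(scfg$enzyme_a_site))

  # --- stage: simulate ------------------------------------------------
  if (done(p$male_fa, p$female_fa, p$r1)) {
    note("simulate: outputs exist, skipping")
  } else {
    note("simulate: genomes, digestion, reads")
    gp <- build_genomes(scfg)
    inds <- sim_individuals(scfg)
    frags <- list(
      female = size_select(digest_genome(gp$female_genome,
                                         scfg$enzyme_a_site,
                                         scfg$enzyme_b_site,
                                         scfg$enzyme_a_cut,
                                         scfg$enzyme_b_cut), scfg),
      male = size_select(digest_genome(gp$male_genome,
                                       scfg$enzyme_a_site,
                                       scfg$enzyme_b_site,
                                       scfg$enzyme_a_cut,
                                       scfg$enzyme_b_cut), scfg)
    )
    reads <- simulate_reads(frags, inds, scfg)
    write_fasta(c(male = gp$male_genome), p$male_fa)
    write_fasta(c(female = gp$female_genome), p$female_fa)
    write_tsv(gp$w_regions, p$truth, hdr)
    write_tsv(inds, p$mids, hdr)
    write_tsv(data.frame(individual_id = inds$individual_id,
                         sex = inds$sex, group = "simulated",
                         stringsAsFactors = FALSE),
              p$phenotype, hdr)
    write_fastq(reads$r1, p$r1)
    write_fastq(reads$r2, p$r2)
  }
  if (!file.exists(p$mids)) {
    stop("pipeline stage 'preprocess': MID table missing: ", p$mids,
         call. = FALSE)
  }
  mids <- read_mid_table(p$mids)

  # --- stage: preprocess ----------------------------------------------
  cleaned_paths <- file.path(p$cleaned_dir,
                             paste0(mids$individual_id, ".fastq"))
  if (done(cleaned_paths, p$preprocess_summary)) {
    note("preprocess: outputs exist, skipping")
  } else {
    note("preprocess: demultiplex + clean")
    raw <- read_fastq(p$r1)
    dmx <- demultiplex(raw, mids)
    dir.create(p$cleaned_dir, showWarnings = FALSE)
    summaries <- list()
    for (i in seq_len(nrow(mids))) {
      id <- mids$individual_id[i]
      sub <- dmx$assigned[dmx$assigned$individual_id == id, , drop = FALSE]
      qs <- if (nrow(sub)) quality_summary(sub) else
        data.frame(read_count = 0L, base_count = 0L, q20_pct = 0,
                   q30_pct = 0)
      cleaned <- clean_reads(sub,
                             tag_length = config$preprocess$tag_length,
                             max_n_fraction = config$preprocess$max_n_fraction,
                             residual_motif = residual,
                             keep_residual = config$preprocess$keep_residual)
      write_fastq(cleaned, file.path(p$cleaned_dir, paste0(id, ".fastq")))
      summaries[[id]] <- data.frame(
        individual_id = id, sex = mids$sex[i],
        raw_reads = qs$read_count, raw_base_pairs = qs$base_count,
        cleaned_reads = nrow(cleaned),
        q20_pct = qs$q20_pct, q30_pct = qs$q30_pct,
        stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, summaries), p$preprocess_summary, hdr)
  }
  prep <- read_tsv(p$preprocess_summary)

  # --- stage: catalog -------------------------------------------------
  catalog_paths <- file.path(p$catalog_dir,
                             paste0(mids$individual_id, ".tsv.gz"))
  if (done(catalog_paths, p$run_summary)) {
    note("catalog: outputs exist, skipping")
  } else {
    note("catalog: stacking tags")
    dir.create(p$catalog_dir, showWarnings = FALSE)
    run_rows <- list()
    for (i in seq_len(nrow(mids))) {
      id <- mids$individual_id[i]
      cleaned <- read_fastq(file.path(p$cleaned_dir, paste0(id, ".fastq")))
      cat_i <- stack_tags(cleaned, canonicalize = config$tagcat$canonicalize,
                          individual_id = id)
      write_catalog(cat_i, file.path(p$catalog_dir,
                                     paste0(id, ".tsv.gz")), hdr)
      pr <- prep[prep$individual_id == id, ]
      run_rows[[id]] <- summarize_run(
        cat_i, raw_read_count = pr$raw_reads,
        raw_base_count = pr$raw_base_pairs,
        q_summary = data.frame(q20_pct = pr$q20_pct, q30_pct = pr$q30_pct),
        genome_size = config$tagcat$genome_size, sex = mids$sex[i])
    }
    write_tsv(do.call(rbind, run_rows), p$run_summary, hdr)
  }

  # --- stage: subtract ------------------------------------------------
  if (done(p$screen, p$markers_fa, p$markers_tsv)) {
    note("subtract: outputs exist, skipping")
  } else {
    note("subtract: cross-sex screen + genome filter")
    catalogs <- lapply(stats::setNames(catalog_paths, mids$individual_id),
                       read_catalog)
    src_sex <- config$subtract$source_sex
    opp_sex <- if (src_sex == "female") "male" else "female"
    src <- catalogs[mids$individual_id[mids$sex == src_sex]]
    opp <- catalogs[mids$individual_id[mids$sex == opp_sex]]
    screened <- cross_sex_screen(src, opp,
                                 min_depth = config$subtract$min_depth,
                                 source_sex = src_sex)
    opp_genome <- read_fasta(if (opp_sex == "male") p$male_fa else
                               p$female_fa)
    screened <- genome_filter(
      screened, opp_genome,
      max_mismatch_fraction = config$subtract$max_mismatch_fraction,
      seed_length = config$subtract$seed_length)
    finals <- final_markers(screened)
    selected <- select_candidates(finals, config$subtract$n_select,
                                  rng_seed = config$rng_seed)
    write_tsv(as.data.frame(screened), p$screen, hdr)
    write_tsv(as.data.frame(selected), p$markers_tsv,
              c(hdr, selection_seed = config$rng_seed))
    write_fasta(stats::setNames(selected$sequence, selected$marker_id),
                p$markers_fa)
  }
  selected <- read_tsv(p$markers_tsv)
  screened <- read_tsv(p$screen)

  # --- stage: genotype ------------------------------------------------
  if (done(p$genotypes)) {
    note("genotype: outputs exist, skipping")
  } else {
    note("genotype: in-silico PCR of ", nrow(selected), " markers")
    if (nrow(selected) == 0L) {
      write_tsv(data.frame(individual_id = mids$individual_id), p$genotypes,
                hdr)
    } else {
      panel <- markers_to_panel(selected,
                                primer_length = config$markers$primer_length)
      male_g <- read_fasta(p$male_fa)
      female_g <- read_fasta(p$female_fa)
      templates <- lapply(stats::setNames(mids$sex, mids$individual_id),
                          function(s) unname(if (s == "female") female_g
                                             else male_g))
      gm <- genotype_panel(templates, panel,
                           size_tolerance_bp = config$markers$size_tolerance_bp)
      df <- data.frame(individual_id = rownames(gm),
                       unclass(gm)[, , drop = FALSE], check.names = FALSE,
                       stringsAsFactors = FALSE)
      write_tsv(df, p$genotypes, hdr)
    }
  }

  # --- stage: reversals -----------------------------------------------
  gdf <- read_tsv(p$genotypes)
  bands <- as.matrix(gdf[, setdiff(names(gdf), "individual_id"),
                         drop = FALSE])
  rownames(bands) <- gdf$individual_id
  system_label <- if (config$subtract$source_sex == "female")
    "ZW_female_marker" else "XY_male_marker"
  genetic <- call_genetic_sex(bands, system_label)
  pheno_df <- read_phenotype_table(p$phenotype)
  phenotypic <- stats::setNames(pheno_df$sex, pheno_df$individual_id)
  report_rev <- detect_reversals(genetic, phenotypic)
  if (!done(p$reversals)) {
    write_tsv(report_rev$discordant, p$reversals, hdr)
  }

  # --- stage: report --------------------------------------------------
  run_sum <- read_tsv(p$run_summary)
  concord <- 100 * mean(genetic[pheno_df$individual_id] == phenotypic)
  report <- data.frame(
    quantity = c(
      paste0("distinct_tags_", run_sum$individual_id),
      "tags_screened", "unmatched_after_read_screen",
      "candidates_after_presence_filter", "markers_after_genome_filter",
      "markers_selected", "genotype_concordance_pct",
      "reversals_female_to_male", "reversals_male_to_female"),
    value = c(
      run_sum$distinct_tags,
      nrow(screened), sum(screened$screen_status == "unmatched"),
      sum(screened$candidate),
      sum(screened$genome_status == "unmapped"),
      nrow(selected), concord,
      report_rev$counts[["female_to_male"]],
      report_rev$counts[["male_to_female"]]),
    stringsAsFactors = FALSE
  )
  write_tsv(report, p$report, hdr)
  files <- unlist(p[c("male_fa", "female_fa", "truth", "mids", "phenotype",
                      "r1", "r2", "preprocess_summary", "run_summary",
                      "screen", "markers_fa", "markers_tsv", "genotypes",
                      "reversals", "report")])
  write_tsv(data.frame(file = basename(files),
                       exists = file.exists(files),
                       stringsAsFactors = FALSE),
            p$manifest, hdr)
  note("done: ", sum(screened$genome_status == "unmapped"),
       " final markers, concordance ", round(concord, 1), "%")
  invisible(list(report = report, screen = screened, markers = selected,
                 genetic_sex = genetic, reversals = report_rev,
                 config_hash = hash, paths = p))
}
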