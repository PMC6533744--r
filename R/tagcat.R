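# Exact stacking of cleaned reads into per-individual RAD-tag catalogs,
# and run-level summary statistics (reads, tags, mean depth, coverage).

#' Stack identical reads into a RAD-tag catalog
#'
#' Identical (optionally strand-canonicalised) cleaned reads are collapsed
#' into distinct tags with supporting depths. Depth is conserved: the depths
#' sum to the number of input reads.
#'
#' @param reads Cleaned reads: a data frame with a `bases` column, or a
#'   character vector of equal-length sequences.
#' @param canonicalize Collapse a sequence with its reverse complement
#'   (strand-safe presence/absence; default `TRUE`).
#' @param individual_id Optional individual label stored on the catalog.
#' @return An object of class `tag_catalog`: a list with `individual_id`,
#'   `depths` (named integer vector, tag sequence -> depth, lexicographic
#'   order), `reads_used`, `distinct_tags`, `tag_length`, `canonical`.
#' @export
stack_tags <- function(reads, canonicalize = TRUE, individual_id = NULL) {
  seqs <- if (is.data.frame(reads)) reads$bases else reads
  if (length(seqs) > 0L && length(unique(nchar(seqs))) != 1L) {
    stop("reads must all have identical length before stacking",
         call. = FALSE)
  }
  if (canonicalize) seqs <- canonical_seq(seqs)
  depths <- if (length(seqs) == 0L) {
    stats::setNames(integer(0), character(0))
  } else {
    tab <- table(seqs)
    stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
  }
  out <- list(individual_id = individual_id,
              depths = depths,
              reads_used = length(seqs),
              distinct_tags = length(depths),
              tag_length = if (length(seqs)) nchar(seqs[1]) else NA_integer_,
              canonical = canonicalize)
  class(out) <- "tag_catalog"
  out
}

#' Tag sequences of a catalog
#' @param catalog A `tag_catalog`.
#' @param min_depth Keep tags supported by at least this many reads.
#' @return Character vector of tag sequences.
#' @export
tag_sequences <- function(catalog, min_depth = 1L) {
  stopifnot(inherits(catalog, "tag_catalog"))
  names(catalog$depths)[catalog$depths >= min_depth]
}

#' @export
print.tag_catalog <- function(x, ...) {
  cat("RAD-tag catalog", if (!is.null(x$individual_id))
    paste0("[", x$individual_id, "]"), "\n")
  cat("  reads used   :", x$reads_used, "\n")
  cat("  distinct tags:", x$distinct_tags, "\n")
  if (x$distinct_tags > 0L) {
    cat("  mean depth   :", round(x$reads_used / x$distinct_tags, 2), "\n")
  }
  invisible(x)
}

#' Summarise one individual's sequencing run
#'
#' Computes the per-individual statistics reported for low-coverage RAD
#' runs: mean tag depth is raw reads divided by distinct tags, and sequence
#' coverage is raw base pairs divided by the genome size (default 5.0e10,
#' a ~50 Gb amphibian genome). Values are kept at full precision; rounding
#' (half-up, 1 dp for depth and 2 dp for coverage) happens only in
#' [format_run_table()].
#'
#' @param catalog A `tag_catalog` (or `NULL` if only raw counts are known,
#'   in which case pass `distinct_tags`).
#' @param raw_read_count,raw_base_count Raw run totals before cleaning.
#' @param q_summary Optional one-row data frame from [quality_summary()].
#' @param genome_size Genome size in bases (default `5e10`).
#' @param sex Optional sex label carried into population tables.
#' @param distinct_tags Tag count override when `catalog` is `NULL`.
#' @return One-row data frame (class `run_summary` rows are plain data).
#' @export
summarize_run <- function(catalog = NULL, raw_read_count, raw_base_count,
                          q_summary = NULL, genome_size = 5e10,
                          sex = NA_character_, distinct_tags = NULL) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  tags <- if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "tag_catalog"))
    catalog$distinct_tags
  } else {
    as.integer(distinct_tags)
  }
  if (is.null(tags) || is.na(tags)) {
    stop("distinct tag count unavailable", call. = FALSE)
  }
  if (tags == 0L) {
    warning("no distinct tags: mean depth undefined, reported as 0",
            call. = FALSE)
    mean_depth <- 0
  } else {
    mean_depth <- raw_read_count / tags
  }
  data.frame(
    individual_id = if (!is.null(catalog) && !is.null(catalog$individual_id))
      catalog$individual_id else NA_character_,
    sex = sex,
    reads = raw_read_count,
    base_pairs = raw_base_count,
    distinct_tags = tags,
    mean_depth = mean_depth,
    coverage = raw_base_count / genome_size,
    q20_pct = if (!is.null(q_summary)) q_summary$q20_pct else NA_real_,
    q30_pct = if (!is.null(q_summary)) q_summary$q30_pct else NA_real_,
    genome_size = genome_size,
    stringsAsFactors = FALSE
  )
}

#' Report-style run table with conventional rounding
#'
#' @param summaries Data frame of rows from [summarize_run()].
#' @return The same rows with `mean_depth` rounded half-up to 1 dp and
#'   `coverage` to 2 dp.
#' @export
format_run_table <- function(summaries) {
  summaries$mean_depth <- round_half_up(summaries$mean_depth, 1)
  summaries$coverage <- round_half_up(summaries$coverage, 2)
  summaries
}

#' Population-level run table with per-sex subtotals
#'
#' Appends per-sex subtotal and sub-average rows plus overall total and
#' average rows to a per-individual run table, mirroring the usual layout
#' of RAD-run summary tables. Aggregates are computed from first principles
#' on the full-precision per-row values (sums for counts, means for rates).
#'
#' @param summaries Data frame of rows from [summarize_run()] with a `sex`
#'   column.
#' @return Data frame with added `row_type` column
#'   (`individual`/`subtotal`/`subaverage`/`total`/`average`).
#' @export
population_summary <- function(summaries) {
  stopifnot("sex" %in% names(summaries))
  agg_row <- function(rows, id, fun) {
    data.frame(individual_id = id, sex = NA_character_,
               reads = fun(rows$reads),
               base_pairs = fun(rows$base_pairs),
               distinct_tags = fun(rows$distinct_tags),
               mean_depth = fun(rows$mean_depth),
               coverage = fun(rows$coverage),
               q20_pct = NA_real_, q30_pct = NA_real_,
               genome_size = rows$genome_size[1],
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (s in unique(summaries$sex)) {
    rows <- summaries[summaries$sex == s, , drop = FALSE]
    rows$row_type <- "individual"
    sub <- agg_row(rows, paste0(s, "_subtotal"), sum)
    sub$row_type <- "subtotal"
    avg <- agg_row(rows, paste0(s, "_subaverage"), mean)
    avg$row_type <- "subaverage"
    out[[s]] <- rbind(rows, sub, avg)
  }
  tot <- agg_row(summaries, "total", sum); tot$row_type <- "total"
  avg <- agg_row(summaries, "average", mean); avg$row_type <- "average"
  res <- rbind(do.call(rbind, out), tot, avg)
  rownames(res) <- NULL
  res
}
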