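# The subtractive discovery computation: screen one sex's tags against the
# opposite sex's reads, then against the opposite sex's genome; the
# survivors are the candidate sex-specific markers.

#' Cross-sex subtractive screen
#'
#' Screens a source sex's tag universe against the opposite sex's
#' per-individual tag sets. A tag is *matched* if its (canonical) sequence
#' occurs in any opposite-sex individual; unmatched tags present in at
#' least `min_source_individuals` source individuals at depth at least
#' `min_depth` become candidate sex-specific markers.
#'
#' @param source_catalogs Named list of `tag_catalog` objects for the source
#'   sex (the sex whose limited sequences are sought, e.g. females under
#'   ZW).
#' @param opposite_catalogs Named list of `tag_catalog` objects for the
#'   opposite sex, or a character vector of opposite-sex tag sequences
#'   (e.g. a full-coverage genome-derived tag set).
#' @param min_source_individuals Minimum number of source individuals a
#'   candidate must be seen in (default: all of them — a genuine
#'   sex-limited marker should be carried by every source-sex sample).
#' @param min_depth Minimum per-individual depth for presence (default 1).
#' @param source_sex Label stored on the markers (default `"female"`).
#' @param reference Optional id of one source catalog whose tags define the
#'   screened universe (the in-silico analogue of screening one reference
#'   individual's assembly); default `NULL` screens the union of all source
#'   catalogs.
#' @return A data frame of class `candidate_markers`, one row per screened
#'   tag, lexicographically ordered by sequence, with columns `marker_id`,
#'   `sequence`, `source_sex`, `n_source_individuals_present`,
#'   `screen_status` (`matched_opposite_reads`/`unmatched`), `candidate`
#'   (logical) and `genome_status` (`not_tested` until [genome_filter()]).
#' @export
cross_sex_screen <- function(source_catalogs, opposite_catalogs,
                             min_source_individuals = length(source_catalogs),
                             min_depth = 1L,
                             source_sex = "female",
                             reference = NULL) {
  stopifnot(length(source_catalogs) > 0L)
  src_tag_sets <- lapply(source_catalogs, tag_sequences, min_depth = min_depth)
  universe <- if (is.null(reference)) {
    sort(unique(unlist(lapply(source_catalogs, tag_sequences),
                       use.names = FALSE)))
  } else {
    if (!reference %in% names(source_catalogs)) {
      stop("reference '", reference, "' is not a source catalog",
           call. = FALSE)
    }
    sort(tag_sequences(source_catalogs[[reference]]))
  }
  opp_tags <- if (is.character(opposite_catalogs)) {
    unique(opposite_catalogs)
  } else {
    unique(unlist(lapply(opposite_catalogs, tag_sequences),
                  use.names = FALSE))
  }
  lens <- unique(nchar(c(universe, opp_tags)))
  if (length(lens) > 1L) {
    stop("tag length mismatch between source and opposite sets",
         call. = FALSE)
  }
  present <- vapply(src_tag_sets, function(s) universe %in% s,
                    logical(length(universe)))
  n_present <- if (length(universe) == 1L) sum(present) else rowSums(present)
  matched <- universe %in% opp_tags
  out <- data.frame(
    marker_id = sprintf("%s_%06d", substr(source_sex, 1L, 1L),
                        seq_along(universe)),
    sequence = universe,
    source_sex = source_sex,
    n_source_individuals_present = as.integer(n_present),
    screen_status = ifelse(matched, "matched_opposite_reads", "unmatched"),
    candidate = !matched & n_present >= min_source_individuals,
    genome_status = "not_tested",
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_markers", "data.frame")
  attr(out, "min_source_individuals") <- min_source_individuals
  attr(out, "min_depth") <- min_depth
  out
}

#' Filter candidates against the opposite sex's genome
#'
#' A candidate is *mapped* if it aligns to either strand of the genome over
#' its full length with at most `max_mismatch_fraction` mismatches, found
#' by exact seed-and-extend (every hit of an exact `seed_length`-mer seed is
#' extended to a full-length ungapped comparison). Unmapped candidates are
#' the final sex-specific markers. Only rows with `candidate == TRUE` are
#' tested; other rows keep `genome_status == "not_tested"`.
#'
#' @param candidates A `candidate_markers` data frame.
#' @param genome Genome sequence (single string) or a named character
#'   vector / `DNAStringSet` of contigs.
#' @param max_mismatch_fraction Mismatch budget as a fraction of tag length
#'   (default 0.10, i.e. up to 11 mismatches on a 110-nt tag).
#' @param seed_length Exact seed length (default 20).
#' @param both_strands Also search the reverse strand (default `TRUE`).
#' @return `candidates` with `genome_status` set to `mapped`/`unmapped` for
#'   tested rows.
#' @export
genome_filter <- function(candidates, genome, max_mismatch_fraction = 0.10,
                          seed_length = 20L, both_strands = TRUE) {
  genome <- as.character(genome)
  if (length(genome) == 0L || !any(nzchar(genome))) {
    stop("genome is empty", call. = FALSE)
  }
  test <- which(candidates$candidate &
                  candidates$screen_status == "unmatched")
  if (length(test) == 0L) return(candidates)
  tag_len <- unique(nchar(candidates$sequence[test]))
  stopifnot(length(tag_len) == 1L)
  seed_length <- as.integer(seed_length)
  if (seed_length > tag_len) {
    stop("seed_length exceeds tag length", call. = FALSE)
  }
  max_mm <- floor(max_mismatch_fraction * tag_len)
  index <- lapply(genome, kmer_index, k = seed_length)
  queries <- candidates$sequence[test]
  mapped <- vapply(queries, function(q) {
    qs <- if (both_strands) c(q, dna_revcomp(q)) else q
    for (ci in seq_along(genome)) {
      for (qq in qs) {
        if (seed_extend_hit(qq, genome[ci], index[[ci]], seed_length,
                            max_mm)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  candidates$genome_status[test] <- ifelse(mapped, "mapped", "unmapped")
  candidates
}

# Hash of all k-mer start positions (1-based) of a sequence.
kmer_index <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(list(kmers = character(0)))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  split(starts, kmers)
}

# TRUE if `query` has an ungapped full-length alignment to `subject` with
# at most `max_mm` mismatches, seeded by any exact k-mer of `query` taken
# at non-overlapping offsets (plus the final window).
seed_extend_hit <- function(query, subject, index, k, max_mm) {
  qlen <- nchar(query)
  slen <- nchar(subject)
  if (slen < qlen) return(FALSE)
  offs <- unique(c(seq(1L, qlen - k + 1L, by = k), qlen - k + 1L))
  qi <- utf8ToInt(query)
  seen <- integer(0)
  for (o in offs) {
    seed <- substr(query, o, o + k - 1L)
    hits <- index[[seed]]
    if (is.null(hits)) next
    ws <- hits - (o - 1L)
    ws <- ws[ws >= 1L & ws + qlen - 1L <= slen]
    ws <- setdiff(ws, seen)
    for (w in ws) {
      window <- substr(subject, w, w + qlen - 1L)
      if (sum(utf8ToInt(window) != qi) <= max_mm) return(TRUE)
    }
    seen <- c(seen, ws)
  }
  FALSE
}

#' Final sex-specific markers
#'
#' @param candidates A `candidate_markers` data frame after
#'   [genome_filter()].
#' @return The subset with `genome_status == "unmapped"`.
#' @export
final_markers <- function(candidates) {
  out <- candidates[candidates$genome_status == "unmapped", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly select candidate markers for validation
#'
#' Uniform sampling without replacement, deterministic for a fixed seed;
#' mirrors picking a subset of discovered markers for PCR validation.
#'
#' @param markers Data frame of markers.
#' @param n Number to select (if `n >= nrow(markers)` all are returned in
#'   their original order).
#' @param rng_seed Integer seed.
#' @return The selected rows (original relative order preserved), with the
#'   seed recorded in attribute `selection_seed`.
#' @export
select_candidates <- function(markers, n, rng_seed = 1L) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (n >= nrow(markers)) {
    attr(markers, "selection_seed") <- rng_seed
    return(markers)
  }
  idx <- with_seed(rng_seed, sort(sample.int(nrow(markers), n)))
  out <- markers[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection_seed") <- rng_seed
  out
}

#' @export
print.candidate_markers <- function(x, ...) {
  cat("Subtractive screen:", nrow(x), "source tags;",
      sum(x$screen_status == "unmatched"), "unmatched;",
      sum(x$candidate), "candidates;",
      sum(x$genome_status == "unmapped"), "unmapped (final markers)\n")
  invisible(x)
}
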