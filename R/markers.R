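# Validated primer panel, in-silico PCR genotyping, genetic sex calling,
# and genetic-vs-phenotypic discordance (sex reversal) reporting.

#' Construct a primer pair
#'
#' @param name Marker name (e.g. `adf340`).
#' @param forward_seq,reverse_seq Primer sequences, 5'-3', at least 15 nt.
#' @param annealing_temp_c Annealing temperature in degrees Celsius
#'   (metadata only).
#' @param expected_product_bp Expected amplicon size in bp.
#' @return One-row data frame usable as a panel row.
#' @export
primer_pair <- function(name, forward_seq, reverse_seq,
                        annealing_temp_c = NA_real_,
                        expected_product_bp) {
  forward_seq <- toupper(forward_seq); reverse_seq <- toupper(reverse_seq)
  assert_dna(forward_seq, "forward primer", allow_n = FALSE)
  assert_dna(reverse_seq, "reverse primer", allow_n = FALSE)
  if (nchar(forward_seq) < 15L || nchar(reverse_seq) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  if (expected_product_bp < nchar(forward_seq) + nchar(reverse_seq)) {
    stop("expected product shorter than the two primers", call. = FALSE)
  }
  data.frame(name = name, forward_seq = forward_seq,
             reverse_seq = reverse_seq,
             annealing_temp_c = annealing_temp_c,
             expected_product_bp = as.integer(expected_product_bp),
             stringsAsFactors = FALSE)
}

#' In-silico PCR
#'
#' Predicts amplicons of a primer pair on a template: every interval where
#' the forward primer matches one strand and the reverse complement of the
#' reverse primer matches the same strand downstream, within
#' `max_product_bp`, with at most `max_primer_mismatches` mismatches per
#' primer. The 3'-terminal base of each primer must match exactly
#' (polymerase extension requires a paired 3' end). Both template strands
#' are tested; coordinates are reported on the plus strand.
#'
#' @param primers One-row data frame from [primer_pair()] (or a list with
#'   `forward_seq`/`reverse_seq`).
#' @param template Template DNA (single string).
#' @param max_product_bp Maximum amplicon size considered (default 2000).
#' @param max_primer_mismatches Mismatch budget per primer, 3' base
#'   excluded from the budget but required to match (default 0).
#' @return Data frame with columns `start`, `end` (0-based half-open on the
#'   plus strand), `product_length` and `strand` (`"+"`/`"-"`).
#' @export
insilico_pcr <- function(primers, template, max_product_bp = 2000L,
                         max_primer_mismatches = 0L) {
  fwd <- toupper(primers$forward_seq)
  rev <- toupper(primers$reverse_seq)
  stopifnot(length(template) == 1L, nzchar(template))
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  L <- nchar(template)
  hits <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") template else dna_revcomp(template)
    f_starts <- primer_site_starts(fwd, subj, max_primer_mismatches,
                                   anchor = "right")
    r_starts <- primer_site_starts(dna_revcomp(rev), subj,
                                   max_primer_mismatches, anchor = "left")
    if (length(f_starts) == 0L || length(r_starts) == 0L) next
    for (sf in f_starts) {
      sr <- r_starts[r_starts >= sf + nchar(fwd)]
      prod <- sr + nchar(rev) - sf
      sr <- sr[prod <= max_product_bp]
      if (length(sr) == 0L) next
      s0 <- sf - 1L                       # 0-based start on this strand
      e0 <- sr + nchar(rev) - 1L          # 0-based half-open end
      if (strand == "-") {
        tmp <- L - e0
        e0 <- L - s0
        s0 <- tmp
      }
      hits[[length(hits) + 1L]] <-
        data.frame(start = s0, end = e0, product_length = e0 - s0,
                   strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      product_length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- unique(out[order(out$start, out$end, out$strand), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# 1-based start positions where `pattern` matches `subject` with at most
# `max_mm` mismatches; the anchored end ("right" = pattern's last base,
# "left" = pattern's first base) must match exactly.
primer_site_starts <- function(pattern, subject, max_mm, anchor) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                max.mismatch = max_mm, with.indels = FALSE)
  starts <- BiocGenerics::start(m)
  if (length(starts) == 0L) return(integer(0))
  plen <- nchar(pattern)
  pos <- if (anchor == "right") starts + plen - 1L else starts
  pchar <- substr(pattern, if (anchor == "right") plen else 1L,
                  if (anchor == "right") plen else 1L)
  ok <- substring(subject, pos, pos) == pchar
  starts[ok]
}

#' Genotype individuals against a primer panel
#'
#' Runs [insilico_pcr()] for every individual x marker combination; an
#' individual shows a *band* for a marker when any template yields a
#' product within `size_tolerance_bp` of the expected size (the
#' gel-resolution analogue).
#'
#' @param templates Named list: one character vector of template sequences
#'   per individual (a genome string, contigs, or a tag set).
#' @param panel Data frame of [primer_pair()] rows.
#' @param size_tolerance_bp Allowed deviation from the expected product
#'   size (default 5).
#' @param max_primer_mismatches Mismatch budget per primer (default 0).
#' @return Logical matrix (individuals x markers) of class
#'   `genotype_matrix`; `TRUE` = band. Individuals with a missing template
#'   get `NA` entries and are listed in attribute `errors`.
#' @export
genotype_panel <- function(templates, panel, size_tolerance_bp = 5L,
                           max_primer_mismatches = 0L) {
  ids <- names(templates)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  mat <- matrix(NA, nrow = length(ids), ncol = nrow(panel),
                dimnames = list(ids, panel$name))
  errors <- character(0)
  for (i in seq_along(ids)) {
    tmpl <- templates[[i]]
    if (is.null(tmpl) || length(tmpl) == 0L || any(is.na(tmpl))) {
      errors <- c(errors, ids[i])
      next
    }
    for (j in seq_len(nrow(panel))) {
      expected <- panel$expected_product_bp[j]
      band <- FALSE
      for (tm in tmpl) {
        prods <- insilico_pcr(panel[j, , drop = FALSE], tm,
                              max_product_bp = expected + size_tolerance_bp,
                              max_primer_mismatches = max_primer_mismatches)
        if (any(abs(prods$product_length - expected) <= size_tolerance_bp)) {
          band <- TRUE
          break
        }
      }
      mat[i, j] <- band
    }
  }
  if (length(errors) > 0L) {
    warning("missing template for: ", paste(errors, collapse = ", "),
            call. = FALSE)
  }
  class(mat) <- c("genotype_matrix", class(mat))
  attr(mat, "errors") <- errors
  mat
}

#' Call genetic sex from a genotype matrix
#'
#' Under a ZW system with female-limited markers a band implies genetic
#' female and its absence genetic male; under an XY system with
#' male-limited markers a band implies genetic male. Multi-marker panels
#' are resolved by majority vote; ties (or all-`NA` rows) give
#' `"indeterminate"`.
#'
#' @param matrix A `genotype_matrix` (logical, `TRUE` = band).
#' @param system `"ZW_female_marker"` or `"XY_male_marker"`.
#' @return Named character vector: `"female"`, `"male"` or
#'   `"indeterminate"` per individual.
#' @export
call_genetic_sex <- function(matrix,
                             system = c("ZW_female_marker",
                                        "XY_male_marker")) {
  system <- match.arg(system)
  marker_sex <- if (system == "ZW_female_marker") "female" else "male"
  other_sex <- if (marker_sex == "female") "male" else "female"
  apply_call <- function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0L) return("indeterminate")
    n_band <- sum(row)
    n_none <- length(row) - n_band
    if (n_band > n_none) marker_sex
    else if (n_none > n_band) other_sex
    else "indeterminate"
  }
  if (ncol(matrix) == 0L) {
    return(stats::setNames(rep("indeterminate", nrow(matrix)),
                           rownames(matrix)))
  }
  stats::setNames(apply(unclass(matrix), 1L, apply_call), rownames(matrix))
}

#' Detect sex reversals (genetic vs phenotypic discordance)
#'
#' Cross-tabulates marker-inferred genetic sex against phenotypic
#' (gonad-determined) sex and lists discordant individuals with the
#' reversal direction: a genetic female with male phenotype is a
#' `female_to_male` reversal (e.g. temperature-induced masculinisation),
#' a genetic male with female phenotype is `male_to_female` (e.g.
#' estradiol-induced feminisation).
#'
#' @param genetic Named character vector from [call_genetic_sex()].
#' @param phenotypic Named character vector (`"female"`/`"male"`), same ids.
#' @return Object of class `reversal_report`: list with `crosstab`
#'   (phenotypic x genetic table), `discordant` (data frame with
#'   `individual_id`, `phenotypic_sex`, `genetic_sex`, `direction`),
#'   `counts` (named: `female_to_male`, `male_to_female`) and `n`.
#' @export
detect_reversals <- function(genetic, phenotypic) {
  if (is.null(names(genetic)) || is.null(names(phenotypic)) ||
      !setequal(names(genetic), names(phenotypic))) {
    stop("genetic and phenotypic sex must cover the same individual ids",
         call. = FALSE)
  }
  ids <- names(phenotypic)
  gen <- genetic[ids]
  crosstab <- table(
    phenotypic = factor(phenotypic, levels = c("female", "male")),
    genetic = factor(gen, levels = c("female", "male", "indeterminate"))
  )
  disc <- ids[gen %in% c("female", "male") & gen != phenotypic]
  discordant <- data.frame(
    individual_id = disc,
    phenotypic_sex = unname(phenotypic[disc]),
    genetic_sex = unname(gen[disc]),
    direction = ifelse(gen[disc] == "female", "female_to_male",
                       "male_to_female"),
    stringsAsFactors = FALSE
  )
  rownames(discordant) <- NULL
  counts <- c(female_to_male = sum(discordant$direction == "female_to_male"),
              male_to_female = sum(discordant$direction == "male_to_female"))
  out <- list(crosstab = crosstab, discordant = discordant,
              counts = counts, n = length(ids))
  class(out) <- "reversal_report"
  out
}

#' @export
print.reversal_report <- function(x, ...) {
  cat("Sex-reversal report (", x$n, " individuals)\n", sep = "")
  print(x$crosstab)
  cat("Reversals: ", x$counts[["female_to_male"]], " female_to_male, ",
      x$counts[["male_to_female"]], " male_to_female\n", sep = "")
  if (nrow(x$discordant) > 0L) {
    cat("Discordant individuals:\n")
    print(x$discordant, row.names = FALSE)
  }
  invisible(x)
}

#' Derive a primer pair from a discovered marker
#'
#' Uses the first and last `primer_length` bases of the marker sequence as
#' forward and reverse primers, so the expected product is the full marker
#' length — the in-silico analogue of designing primers on a validated
#' sex-specific tag.
#'
#' @param markers Data frame with `marker_id` and `sequence` columns.
#' @param primer_length Primer length (default 20).
#' @return Panel data frame of [primer_pair()] rows.
#' @export
markers_to_panel <- function(markers, primer_length = 20L) {
  stopifnot(nrow(markers) > 0L)
  tag_len <- nchar(markers$sequence)
  do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
    primer_pair(
      name = markers$marker_id[i],
      forward_seq = substr(markers$sequence[i], 1L, primer_length),
      reverse_seq = dna_revcomp(substr(markers$sequence[i],
                                       tag_len[i] - primer_length + 1L,
                                       tag_len[i])),
      expected_product_bp = tag_len[i]
    )
  }))
}
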