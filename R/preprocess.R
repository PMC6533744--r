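# Demultiplexing by inline barcode, read cleaning to fixed-length RAD-tags,
# and per-run quality summaries.

#' Demultiplex reads by inline barcode (MID)
#'
#' Assigns each read to the individual whose MID exactly matches the read
#' start; with nested MIDs of different lengths the longest matching MID
#' wins. Assigned reads have their MID removed. Every input read lands in
#' exactly one output stream (assigned or unassigned).
#'
#' @param reads Data frame with columns `read_id`, `bases`, `qualities`.
#' @param mid_table Data frame with columns `individual_id`, `sex`, `mid`
#'   (MIDs unique; lengths may differ).
#' @return A list with data frames `assigned` (plus `individual_id` column,
#'   MID stripped) and `unassigned`.
#' @export
demultiplex <- function(reads, mid_table) {
  stopifnot(all(c("individual_id", "mid") %in% names(mid_table)))
  if (anyDuplicated(mid_table$mid)) {
    stop("MID table is ambiguous: duplicate MIDs", call. = FALSE)
  }
  if (anyDuplicated(mid_table$individual_id)) {
    stop("MID table is ambiguous: duplicate individual ids", call. = FALSE)
  }
  n <- nrow(reads)
  who <- rep(NA_character_, n)
  midlen <- rep(NA_integer_, n)
  ord <- order(-nchar(mid_table$mid))  # longest match wins
  for (i in ord) {
    hit <- is.na(who) & startsWith(reads$bases, mid_table$mid[i])
    who[hit] <- mid_table$individual_id[i]
    midlen[hit] <- nchar(mid_table$mid[i])
  }
  assigned <- reads[!is.na(who), , drop = FALSE]
  ml <- midlen[!is.na(who)]
  assigned$bases <- substring(assigned$bases, ml + 1L)
  assigned$qualities <- substring(assigned$qualities, ml + 1L)
  assigned$individual_id <- who[!is.na(who)]
  unassigned <- reads[is.na(who), , drop = FALSE]
  rownames(assigned) <- rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}

#' Clean reads into fixed-length RAD-tags
#'
#' Applies the screening rules used for presence/absence tag comparison:
#' reads must start with the enzyme restriction residue (missing-site reads
#' are removed), are trimmed to a fixed tag length, and are removed when the
#' trimmed tag contains strictly more than `max_n_fraction` unknown (N)
#' bases. By default the restriction residue is retained, so every tag
#' starts with it, as in standard RAD-tags.
#'
#' @param reads Data frame with columns `read_id`, `bases`, `qualities`
#'   (MID already stripped); an `individual_id` column is carried through.
#' @param tag_length Fixed tag length in bases (default 110).
#' @param max_n_fraction Maximum tolerated N fraction on the trimmed tag;
#'   strictly greater is removed (default 0.10).
#' @param residual_motif Restriction residue expected at position 1
#'   (default `AATTC`, the EcoRI residue).
#' @param keep_residual Keep the residue inside the tag (default `TRUE`);
#'   when `FALSE` the residue is stripped before trimming.
#' @return Data frame of surviving reads, all exactly `tag_length` bases.
#' @export
clean_reads <- function(reads, tag_length = 110L, max_n_fraction = 0.10,
                        residual_motif = "AATTC", keep_residual = TRUE) {
  tag_length <- as.integer(tag_length)
  if (tag_length <= 0L) stop("tag_length must be positive", call. = FALSE)
  offset <- if (keep_residual) 0L else nchar(residual_motif)
  keep <- startsWith(reads$bases, residual_motif) &
    nchar(reads$bases) >= offset + tag_length
  out <- reads[keep, , drop = FALSE]
  out$bases <- substr(out$bases, offset + 1L, offset + tag_length)
  out$qualities <- substr(out$qualities, offset + 1L, offset + tag_length)
  n_count <- nchar(out$bases) - nchar(gsub("N", "", out$bases, fixed = TRUE))
  out <- out[n_count / tag_length <= max_n_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-run sequencing quality summary
#'
#' @param reads Data frame with columns `bases` and `qualities`
#'   (Phred+33-encoded).
#' @return One-row data frame with `read_count`, `base_count`, `q20_pct`
#'   and `q30_pct` (percent of bases with Phred quality >= 20 / >= 30).
#' @export
quality_summary <- function(reads) {
  if (nrow(reads) == 0L) {
    warning("empty read set: quality summary is all zeros", call. = FALSE)
    return(data.frame(read_count = 0L, base_count = 0L,
                      q20_pct = 0, q30_pct = 0))
  }
  q <- utf8ToInt(paste(reads$qualities, collapse = "")) - 33L
  data.frame(read_count = nrow(reads),
             base_count = length(q),
             q20_pct = 100 * mean(q >= 20L),
             q30_pct = 100 * mean(q >= 30L))
}
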