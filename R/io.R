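# File-format plumbing: FASTA/FASTQ via Biostrings, TSV tables with
# provenance comment headers.

#' Write reads to FASTQ (Phred+33)
#' @param reads Data frame with `read_id`, `bases`, `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qualities)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path.
#' @return Data frame with `read_id`, `bases`, `qualities`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             bases = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

# TSV with '# key: value' provenance comment headers.
write_tsv <- function(df, path, header = character(0)) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) {
    writeLines(paste0("# ", names(header), ": ", unname(header)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a MID (barcode) table
#'
#' @param path TSV with columns `individual_id`, `sex`, `mid`.
#' @return Data frame.
#' @export
read_mid_table <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("individual_id", "sex", "mid") %in% names(df)))
  df$mid <- toupper(df$mid)
  df
}

#' Read a phenotypic-sex table
#'
#' @param path TSV with columns `individual_id`, `sex` and optionally
#'   `group`.
#' @return Data frame.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("individual_id", "sex") %in% names(df)))
  df
}

#' Read a primer-panel table
#'
#' @param path TSV with columns `name`, `forward_seq`, `reverse_seq`,
#'   optionally `annealing_temp_c`, and `expected_product_bp`.
#' @return Panel data frame of [primer_pair()] rows.
#' @export
read_primer_panel <- function(path) {
  df <- read_tsv(path)
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$name[i], df$forward_seq[i], df$reverse_seq[i],
                annealing_temp_c = df$annealing_temp_c[i] %||% NA_real_,
                expected_product_bp = df$expected_product_bp[i])
  }))
}

#' Write a tag catalog as TSV
#' @param catalog A `tag_catalog`.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @param header Named character vector of provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, header = character(0)) {
  df <- data.frame(sequence = names(catalog$depths),
                   depth = unname(catalog$depths),
                   stringsAsFactors = FALSE)
  write_tsv(df, path, c(header,
                        individual_id = catalog$individual_id %||% "NA",
                        reads_used = catalog$reads_used,
                        canonical = catalog$canonical))
  invisible(path)
}

#' Read a tag catalog from TSV
#' @param path Catalog path written by [write_catalog()].
#' @param individual_id Optional individual label (defaults from filename).
#' @return A `tag_catalog`.
#' @export
read_catalog <- function(path, individual_id = NULL) {
  df <- read_tsv(path)
  if (is.null(individual_id)) {
    individual_id <- sub("\\.tsv(\\.gz)?$", "", basename(path))
  }
  depths <- stats::setNames(as.integer(df$depth), df$sequence)
  depths <- depths[order(names(depths))]
  out <- list(individual_id = individual_id, depths = depths,
              reads_used = sum(depths), distinct_tags = length(depths),
              tag_length = if (length(depths)) nchar(names(depths)[1])
                           else NA_integer_,
              canonical = NA)
  class(out) <- "tag_catalog"
  out
}
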