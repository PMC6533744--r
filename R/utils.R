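# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so deterministic simulation does not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Random DNA sequence
#' @param n Length in bases.
#' @return A single uppercase A/C/G/T string.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; handles IUPAC N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (strand-invariant) form of DNA sequences
#'
#' The canonical form is the lexicographic minimum of a sequence and its
#' reverse complement, making presence/absence comparisons strand-safe.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of canonical sequences.
#' @export
canonical_seq <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- dna_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Half-up rounding (report-time only; full precision is kept internally).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " must be uppercase ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T",
         " (offending value: ", x[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(x)
}
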