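# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different code paths from the package internals:
# motif scanning by vectorised substring comparison (not gregexpr), genome
# mapping via Biostrings::matchPattern (not seed-and-extend), and amplicon
# prediction by a naive sliding window (not matchPattern).

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

str_mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# All motif start offsets (0-based) by exhaustive window comparison.
scan_motif <- function(sequence, motif) {
  L <- nchar(sequence)
  k <- nchar(motif)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  which(substring(sequence, starts, starts + k - 1L) == motif) - 1L
}

# Exhaustive digestion oracle: every fragment between adjacent cuts, with
# enzyme labels; mixed_only keeps A/B-flanked fragments.
oracle_digest <- function(sequence, site_a = "GAATTC", site_b = "CATG",
                          cut_a = 1L, cut_b = 4L, mixed_only = TRUE) {
  cuts <- rbind(
    data.frame(pos = scan_motif(sequence, site_a) + cut_a, enzyme = "A"),
    data.frame(pos = scan_motif(sequence, site_b) + cut_b, enzyme = "B")
  )
  cuts <- cuts[order(cuts$pos, cuts$enzyme), , drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]
  n <- nrow(cuts)
  if (n < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), flank_left = character(0),
                      flank_right = character(0)))
  }
  out <- data.frame(start = cuts$pos[-n], end = cuts$pos[-1],
                    flank_left = cuts$enzyme[-n],
                    flank_right = cuts$enzyme[-1],
                    stringsAsFactors = FALSE)
  out <- out[out$end > out$start, , drop = FALSE]
  if (mixed_only) out <- out[out$flank_left != out$flank_right, , drop = FALSE]
  out$sequence <- substring(sequence, out$start + 1L, out$end)
  rownames(out) <- NULL
  out[, c("start", "end", "sequence", "flank_left", "flank_right")]
}

# Full Hamming-scan mapping oracle (every genome offset, both strands).
oracle_mapped <- function(query, genome, max_mm) {
  hit <- function(q) {
    length(Biostrings::matchPattern(Biostrings::DNAString(q),
                                    Biostrings::DNAString(genome),
                                    max.mismatch = max_mm,
                                    with.indels = FALSE)) > 0L
  }
  hit(query) || hit(dna_revcomp(query))
}

# Naive sliding-window in-silico PCR oracle.
oracle_pcr <- function(fwd, rev, template, max_product, max_mm = 0L) {
  L <- nchar(template)
  site_hits <- function(pat, subj, anchor) {
    k <- nchar(pat)
    s <- integer(0)
    for (i in seq_len(nchar(subj) - k + 1L)) {
      w <- substr(subj, i, i + k - 1L)
      apos <- if (anchor == "right") k else 1L
      if (substr(w, apos, apos) != substr(pat, apos, apos)) next
      if (str_mismatches(w, pat) <= max_mm) s <- c(s, i)
    }
    s
  }
  rows <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") template else dna_revcomp(template)
    fs <- site_hits(fwd, subj, "right")
    rs <- site_hits(dna_revcomp(rev), subj, "left")
    for (sf in fs) {
      for (sr in rs) {
        if (sr < sf + nchar(fwd)) next
        prod <- sr + nchar(rev) - sf
        if (prod > max_product) next
        s0 <- sf - 1L
        e0 <- sr + nchar(rev) - 1L
        if (strand == "-") { tmp <- L - e0; e0 <- L - s0; s0 <- tmp }
        rows[[length(rows) + 1L]] <-
          data.frame(start = s0, end = e0, product_length = e0 - s0,
                     strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      product_length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out[order(out$start, out$end, out$strand), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Catalog built directly from a character vector of tag sequences.
catalog_of <- function(tags, id = "x", canonicalize = FALSE) {
  stack_tags(tags, canonicalize = canonicalize, individual_id = id)
}

# Small simulated ZW population used by several test files.
small_population <- function(seed = 42L, genome_length = 100000L,
                             n_w_regions = 3L) {
  cfg <- sim_config(genome_length = genome_length, n_females = 4L,
                    n_males = 4L, n_w_regions = n_w_regions,
                    w_region_length = 2000L, mean_depth = 5,
                    error_rate = 0, rng_seed = seed)
  gp <- build_genomes(cfg)
  frags <- list(
    female = size_select(digest_genome(gp$female_genome), cfg),
    male = size_select(digest_genome(gp$male_genome), cfg)
  )
  inds <- sim_individuals(cfg)
  list(cfg = cfg, gp = gp, frags = frags, inds = inds)
}

# Per-individual catalogs from simulated reads, via the full preprocess
# path (demultiplex -> clean -> stack).
population_catalogs <- function(pop) {
  reads <- simulate_reads(pop$frags, pop$inds, pop$cfg)
  dmx <- demultiplex(reads$r1[, c("read_id", "bases", "qualities")],
                     pop$inds)
  cleaned <- clean_reads(dmx$assigned)
  split_reads <- split(cleaned, cleaned$individual_id)
  cats <- lapply(names(split_reads), function(id) {
    stack_tags(split_reads[[id]], canonicalize = TRUE, individual_id = id)
  })
  names(cats) <- names(split_reads)
  cats
}

# Canonical 110-nt tags of the planted (guaranteed size-selected) W
# fragments: the left flank is enzyme A by construction.
planted_tags <- function(pop, tag_length = 110L) {
  fr <- data.frame(sequence = pop$gp$w_regions$fragment_seq,
                   flank_left = "A", flank_right = "B",
                   stringsAsFactors = FALSE)
  canonical_seq(substr(fragment_template(fr, pop$cfg), 1L, tag_length))
}
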