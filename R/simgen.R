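# Synthetic ddRAD data generator: diploid-free genome pair with
# heterogametic-sex-limited (W) insertions, in-silico double digestion,
# size selection, and barcoded read simulation.

#' Simulation configuration
#'
#' Parameters of the synthetic ddRAD experiment. Defaults emulate a
#' two-enzyme (EcoRI + NlaIII) library with 400-600 bp gel selection
#' (including 75 bp of adapter, i.e. a 325-525 bp insert window) sequenced
#' as 150 bp paired-end reads with inline barcodes, at sub-1x per-individual
#' coverage as used for presence/absence marker discovery in very large
#' genomes.
#'
#' @param genome_length Length of the shared (Z-like) genome in bases.
#' @param n_females,n_males Number of individuals per sex.
#' @param n_w_regions Number of female-limited (W) regions planted.
#' @param w_region_length Length of each planted region in bases.
#' @param enzyme_a_site Recognition motif of the rare cutter carrying the
#'   sequencing adapter (default EcoRI, `GAATTC`).
#' @param enzyme_b_site Recognition motif of the frequent cutter
#'   (default NlaIII, `CATG`).
#' @param enzyme_a_cut,enzyme_b_cut Cut offset within each motif, in bases
#'   from the motif start (EcoRI cuts G^AATTC, offset 1; NlaIII cuts CATG^,
#'   offset 4).
#' @param select_min,select_max Inclusive gel-size window in bp, measured as
#'   insert length plus `adapter_length`.
#' @param adapter_length Total adapter length included in the gel size (bp).
#' @param read_length Read length in bp.
#' @param mean_depth Mean reads per retained fragment per individual
#'   (Poisson).
#' @param error_rate Per-base substitution probability.
#' @param rng_seed Integer seed; all generator output is byte-identical for
#'   a fixed configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 100000L,
                       n_females = 4L, n_males = 4L,
                       n_w_regions = 3L, w_region_length = 2000L,
                       enzyme_a_site = "GAATTC", enzyme_b_site = "CATG",
                       enzyme_a_cut = 1L, enzyme_b_cut = 4L,
                       select_min = 400L, select_max = 600L,
                       adapter_length = 75L, read_length = 150L,
                       mean_depth = 5, error_rate = 0,
                       rng_seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    n_w_regions = as.integer(n_w_regions),
    w_region_length = as.integer(w_region_length),
    enzyme_a_site = toupper(enzyme_a_site),
    enzyme_b_site = toupper(enzyme_b_site),
    enzyme_a_cut = as.integer(enzyme_a_cut),
    enzyme_b_cut = as.integer(enzyme_b_cut),
    select_min = as.integer(select_min), select_max = as.integer(select_max),
    adapter_length = as.integer(adapter_length),
    read_length = as.integer(read_length),
    mean_depth = mean_depth, error_rate = error_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (genome_length <= 0L || w_region_length <= 0L || read_length <= 0L ||
        adapter_length < 0L || select_min <= 0L || select_max <= 0L) {
      stop("all lengths must be positive", call. = FALSE)
    }
    if (n_females < 0L || n_males < 0L || n_w_regions < 0L) {
      stop("counts must be non-negative", call. = FALSE)
    }
    if (select_min > select_max) {
      stop("select_min must not exceed select_max", call. = FALSE)
    }
    if (error_rate < 0 || error_rate >= 1) {
      stop("error_rate must lie in [0, 1)", call. = FALSE)
    }
    if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
    if (n_w_regions * w_region_length >= genome_length) {
      stop("total planted W length must be smaller than the genome",
           call. = FALSE)
    }
    assert_dna(enzyme_a_site, "enzyme_a_site", allow_n = FALSE)
    assert_dna(enzyme_b_site, "enzyme_b_site", allow_n = FALSE)
    if (enzyme_a_cut < 0L || enzyme_a_cut > nchar(enzyme_a_site) ||
        enzyme_b_cut < 0L || enzyme_b_cut > nchar(enzyme_b_site)) {
      stop("cut offsets must lie within their motifs", call. = FALSE)
    }
    # a planted fragment (residual + core + B site) plus the motif head and
    # protective pads must fit inside one W region
    need <- (select_max - adapter_length) + nchar(enzyme_a_site) + 14L
    if (n_w_regions > 0L && w_region_length < need) {
      stop("w_region_length too short to host a size-selected fragment (need >= ",
           need, ")", call. = FALSE)
    }
  })
  invisible(cfg)
}

# Mutate one base of every motif occurrence not listed in `keep` (0-based
# motif start offsets), repeating until no spurious occurrence remains.
scrub_motifs <- function(seq, motifs, keep = integer(0)) {
  for (iter in 1:50) {
    hits <- integer(0)
    for (m in motifs) {
      g <- gregexpr(m, seq, fixed = TRUE)[[1]]
      if (g[1] != -1L) hits <- c(hits, as.integer(g) - 1L)
    }
    spurious <- setdiff(hits, keep)
    if (length(spurious) == 0L) return(seq)
    for (p in spurious) {
      i <- p + 2L  # mutate the second base of the occurrence (1-based index)
      old <- substr(seq, i, i)
      repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      substr(seq, i, i) <- repl
    }
  }
  stop("failed to scrub spurious restriction sites from planted region",
       call. = FALSE)
}

#' Build a synthetic ZW genome pair with planted female-limited regions
#'
#' The male genome is a random shared sequence; the female genome carries
#' `n_w_regions` additional insertions. Each planted region is constructed
#' around one guaranteed ddRAD-valid fragment: an enzyme-A cut site followed
#' by a clean core and an enzyme-B site, with the insert length drawn
#' uniformly from the size-selection window, so every region is discoverable
#' after digestion and size selection.
#'
#' @param config A [sim_config()].
#' @return An object of class `genome_pair`: a list with `male_genome`,
#'   `female_genome`, `shared_sequence` and a `w_regions` data frame of
#'   planted truth (0-based half-open coordinates on the female genome,
#'   including the coordinates and sequence of the guaranteed fragment).
#' @export
build_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    shared <- random_dna(config$genome_length)
    n <- config$n_w_regions
    if (n == 0L) {
      out <- list(male_genome = shared, female_genome = shared,
                  shared_sequence = shared,
                  w_regions = empty_w_truth())
      class(out) <- "genome_pair"
      return(out)
    }
    site_a <- config$enzyme_a_site
    site_b <- config$enzyme_b_site
    a_res <- substr(site_a, config$enzyme_a_cut + 1L, nchar(site_a))
    ins_pts <- sort(sample.int(config$genome_length - 1L, n))
    regions <- vector("list", n)
    for (i in seq_len(n)) {
      insert_len <- sample(seq(config$select_min - config$adapter_length,
                               config$select_max - config$adapter_length), 1L)
      core_len <- insert_len - nchar(a_res) - nchar(site_b)
      slack <- config$w_region_length - insert_len - config$enzyme_a_cut
      lp <- sample.int(slack - 7L, 1L) + 6L  # both pads at least 7 nt
      rp <- slack - lp
      region <- paste0(random_dna(lp),
                       site_a, random_dna(core_len), site_b,
                       random_dna(rp))
      # keep exactly the planted A and B sites; everything else is scrubbed
      # so the planted fragment cannot be split by a chance cut
      keep <- c(lp, lp + nchar(site_a) + core_len)
      region <- scrub_motifs(region, c(site_a, site_b), keep)
      regions[[i]] <- list(insertion_point = ins_pts[i], lp = lp,
                           insert_len = insert_len, region = region)
    }
    # splice regions into the shared sequence at increasing offsets
    pieces <- character(0)
    prev <- 0L
    offset <- 0L
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      r <- regions[[i]]
      pieces <- c(pieces, substr(shared, prev + 1L, r$insertion_point))
      start_f <- r$insertion_point + offset
      frag_start <- start_f + r$lp + config$enzyme_a_cut
      frag_end <- frag_start + r$insert_len
      truth[[i]] <- data.frame(
        region_id = sprintf("W%02d", i),
        insertion_point = r$insertion_point,
        start = start_f,
        end = start_f + config$w_region_length,
        fragment_start = frag_start,
        fragment_end = frag_end,
        fragment_seq = substr(r$region, r$lp + config$enzyme_a_cut + 1L,
                              r$lp + config$enzyme_a_cut + r$insert_len),
        region_seq = r$region,
        stringsAsFactors = FALSE
      )
      pieces <- c(pieces, r$region)
      prev <- r$insertion_point
      offset <- offset + config$w_region_length
    }
    pieces <- c(pieces, substr(shared, prev + 1L, config$genome_length))
    female <- paste(pieces, collapse = "")
    out <- list(male_genome = shared, female_genome = female,
                shared_sequence = shared,
                w_regions = do.call(rbind, truth))
    class(out) <- "genome_pair"
    out
  })
}

empty_w_truth <- function() {
  data.frame(region_id = character(0), insertion_point = integer(0),
             start = integer(0), end = integer(0),
             fragment_start = integer(0), fragment_end = integer(0),
             fragment_seq = character(0), region_seq = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("ZW genome pair\n")
  cat("  shared length :", nchar(x$male_genome), "bp\n")
  cat("  female length :", nchar(x$female_genome), "bp\n")
  cat("  planted W regions:", nrow(x$w_regions), "\n")
  invisible(x)
}

#' In-silico double digestion
#'
#' Cuts a sequence at every occurrence of the two enzyme motifs (at their
#' configured cut offsets) and returns the fragments flanked by one cut of
#' each enzyme, the only fragments that acquire both adapters in a ddRAD
#' library. Fragments between two cuts of the same enzyme, and terminal
#' fragments bounded by a sequence end, are discarded.
#'
#' @param sequence Uppercase A/C/G/T/N string.
#' @param site_a,site_b Enzyme recognition motifs (A/C/G/T).
#' @param cut_a,cut_b Cut offsets within each motif (bases from motif start).
#' @return A data frame with columns `start`, `end` (0-based half-open),
#'   `sequence`, `flank_left`, `flank_right` (enzyme labels `"A"`/`"B"`).
#' @export
digest_genome <- function(sequence, site_a = "GAATTC", site_b = "CATG",
                          cut_a = 1L, cut_b = 4L) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  assert_dna(sequence, "sequence", allow_n = TRUE)
  assert_dna(site_a, "site_a", allow_n = FALSE)
  assert_dna(site_b, "site_b", allow_n = FALSE)
  cuts <- enzyme_cuts(sequence, site_a, site_b, cut_a, cut_b)
  n <- nrow(cuts)
  if (n < 2L) return(empty_fragments())
  start <- cuts$pos[-n]
  end <- cuts$pos[-1L]
  left <- cuts$enzyme[-n]
  right <- cuts$enzyme[-1L]
  keep <- left != right & end > start
  if (!any(keep)) return(empty_fragments())
  frags <- data.frame(start = start[keep], end = end[keep],
                      sequence = substring(sequence, start[keep] + 1L,
                                           end[keep]),
                      flank_left = left[keep], flank_right = right[keep],
                      stringsAsFactors = FALSE)
  rownames(frags) <- NULL
  frags
}

# All cut coordinates (0-based) with enzyme labels, position-sorted.
# A cut claimed by both enzymes at the same coordinate is labelled "A".
enzyme_cuts <- function(sequence, site_a, site_b, cut_a, cut_b) {
  pos_of <- function(site, off) {
    g <- gregexpr(site, sequence, fixed = TRUE)[[1]]
    if (g[1] == -1L) integer(0) else as.integer(g) - 1L + off
  }
  pa <- pos_of(site_a, cut_a)
  pb <- pos_of(site_b, cut_b)
  cuts <- data.frame(pos = c(pa, pb),
                     enzyme = c(rep("A", length(pa)), rep("B", length(pb))),
                     stringsAsFactors = FALSE)
  cuts <- cuts[order(cuts$pos, cuts$enzyme), , drop = FALSE]
  cuts[!duplicated(cuts$pos), , drop = FALSE]
}

empty_fragments <- function() {
  data.frame(start = integer(0), end = integer(0), sequence = character(0),
             flank_left = character(0), flank_right = character(0),
             stringsAsFactors = FALSE)
}

#' Gel size selection
#'
#' Retains fragments whose gel size (insert length plus adapter length)
#' falls inside the inclusive selection window; input order is preserved.
#'
#' @param fragments Data frame from [digest_genome()].
#' @param config A [sim_config()] supplying `select_min`, `select_max` and
#'   `adapter_length`.
#' @return The retained subset of `fragments`.
#' @export
size_select <- function(fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  gel <- nchar(fragments$sequence) + config$adapter_length
  out <- fragments[gel >= config$select_min & gel <= config$select_max, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-1 template of a ddRAD fragment
#'
#' Orients each fragment so that sequencing starts at the enzyme-A end:
#' read 1 then begins with the enzyme-A restriction residue (e.g. `AATTC`
#' for EcoRI), as in standard RAD-tags. For fragments whose A cut lies at
#' the right end the template is the reverse complement read off the bottom
#' strand, which (for a palindromic site) regains the overhang bases across
#' the cut.
#'
#' @param fragments Data frame from [digest_genome()].
#' @param config A [sim_config()].
#' @return Character vector of templates, one per fragment.
#' @export
fragment_template <- function(fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(fragments) == 0L) return(character(0))
  site_a <- config$enzyme_a_site
  overhang <- substr(site_a, config$enzyme_a_cut + 1L,
                     nchar(site_a) - config$enzyme_a_cut)
  ifelse(fragments$flank_left == "A",
         fragments$sequence,
         paste0(overhang, dna_revcomp(fragments$sequence)))
}

#' Expected RAD-tags of a fragment set
#'
#' The tag a fragment contributes after cleaning and trimming: the first
#' `tag_length` bases of its read-1 template. Useful as a full-coverage
#' stand-in (every fragment sequenced error-free) and as planted-truth in
#' tests.
#'
#' @param fragments Data frame from [digest_genome()] (or [size_select()]).
#' @param config A [sim_config()].
#' @param tag_length Tag length in bases (default 110).
#' @param canonicalize Return canonical (strand-invariant) forms?
#' @return Character vector of tags; fragments shorter than `tag_length`
#'   are dropped.
#' @export
fragment_tags <- function(fragments, config, tag_length = 110L,
                          canonicalize = TRUE) {
  tmpl <- fragment_template(fragments, config)
  tmpl <- tmpl[nchar(tmpl) >= tag_length]
  tags <- substr(tmpl, 1L, tag_length)
  if (canonicalize) tags <- canonical_seq(tags)
  unique(tags)
}

#' Individual table for a simulated population
#'
#' Assigns each individual a unique inline barcode (MID) of 4-6 nt,
#' mimicking variable-length multiplexing barcodes. Barcodes are generated
#' so that no barcode is a prefix of another barcode followed by the
#' enzyme-A residue, which keeps longest-prefix demultiplexing exact.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `individual_id`, `sex`
#'   (`"female"`/`"male"`) and `mid`.
#' @export
sim_individuals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_females + config$n_males
  a_res <- substr(config$enzyme_a_site, config$enzyme_a_cut + 1L,
                  nchar(config$enzyme_a_site))
  with_seed(config$rng_seed + 7L, {
    mids <- character(0)
    lens <- rep(c(4L, 5L, 6L), length.out = n)
    for (i in seq_len(n)) {
      repeat {
        cand <- random_dna(lens[i])
        ok <- !any(vapply(mids, function(m) {
          startsWith(paste0(m, a_res), cand) || startsWith(paste0(cand, a_res), m)
        }, logical(1)))
        if (ok && !cand %in% mids) break
      }
      mids <- c(mids, cand)
    }
    data.frame(
      individual_id = c(sprintf("F%d", seq_len(config$n_females)),
                        sprintf("M%d", seq_len(config$n_males))),
      sex = c(rep("female", config$n_females), rep("male", config$n_males)),
      mid = mids,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a barcoded ddRAD sequencing run
#'
#' Draws a Poisson(`mean_depth`) number of read pairs per retained fragment
#' per individual. Read 1 is the individual's MID followed by the fragment's
#' read-1 template (enzyme-A residue first), truncated to `read_length`
#' (random bases pad short templates); read 2 reads from the enzyme-B end
#' and is emitted for format fidelity only. Substitution errors are applied
#' i.i.d. at `error_rate`; qualities are constant Phred 37.
#'
#' @param fragments Either a single fragment data frame used for all
#'   individuals, or a named list with elements `female` and `male`.
#' @param individuals Data frame as from [sim_individuals()]
#'   (`individual_id`, `sex`, `mid`; MIDs must be unique).
#' @param config A [sim_config()].
#' @return A list of class `sim_reads` with data frames `r1` and `r2`
#'   (columns `read_id`, `bases`, `qualities`, `individual_id`; the
#'   `individual_id` column is simulation truth and is not written to
#'   FASTQ).
#' @export
simulate_reads <- function(fragments, individuals, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyDuplicated(individuals$mid)) {
    stop("duplicate MIDs in individual table", call. = FALSE)
  }
  frag_for <- function(sex) {
    if (is.data.frame(fragments)) fragments else fragments[[sex]]
  }
  rl <- config$read_length
  qual_char <- rawToChar(as.raw(37L + 33L))
  with_seed(config$rng_seed + 1L, {
    out1 <- list(); out2 <- list()
    for (i in seq_len(nrow(individuals))) {
      ind <- individuals$individual_id[i]
      mid <- individuals$mid[i]
      fr <- frag_for(individuals$sex[i])
      if (nrow(fr) == 0L) next
      tmpl1 <- fragment_template(fr, config)
      tmpl2 <- ifelse(fr$flank_left == "A", dna_revcomp(fr$sequence),
                      fr$sequence)
      counts <- stats::rpois(nrow(fr), config$mean_depth)
      idx <- rep(seq_len(nrow(fr)), counts)
      if (length(idx) == 0L) next
      r1 <- substr(paste0(mid, tmpl1[idx]), 1L, rl)
      r2 <- substr(tmpl2[idx], 1L, rl)
      r1 <- pad_reads(r1, rl)
      r2 <- pad_reads(r2, rl)
      if (config$error_rate > 0) {
        r1 <- apply_substitutions(r1, config$error_rate)
        r2 <- apply_substitutions(r2, config$error_rate)
      }
      copy <- stats::ave(idx, idx, FUN = seq_along)
      ids <- sprintf("%s:frag%05d:%03d", ind, idx, copy)
      qual <- strrep(qual_char, nchar(r1))
      out1[[ind]] <- data.frame(read_id = paste0(ids, "/1"), bases = r1,
                                qualities = qual, individual_id = ind,
                                stringsAsFactors = FALSE)
      out2[[ind]] <- data.frame(read_id = paste0(ids, "/2"), bases = r2,
                                qualities = strrep(qual_char, nchar(r2)),
                                individual_id = ind,
                                stringsAsFactors = FALSE)
    }
    res <- list(r1 = do.call(rbind, out1) %||% empty_reads(),
                r2 = do.call(rbind, out2) %||% empty_reads())
    rownames(res$r1) <- rownames(res$r2) <- NULL
    class(res) <- "sim_reads"
    res
  })
}

pad_reads <- function(reads, read_length) {
  short <- nchar(reads) < read_length
  if (any(short)) {
    reads[short] <- vapply(reads[short], function(r) {
      paste0(r, random_dna(read_length - nchar(r)))
    }, character(1), USE.NAMES = FALSE)
  }
  reads
}

apply_substitutions <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- stats::rbinom(1L, n, error_rate)
    if (k == 0L) return(r)
    pos <- sample.int(n, k)
    for (p in pos) {
      old <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(bases, old), 1L)
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

empty_reads <- function() {
  data.frame(read_id = character(0), bases = character(0),
             qualities = character(0), individual_id = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("Simulated ddRAD run:", nrow(x$r1), "read pairs from",
      length(unique(x$r1$individual_id)), "individuals\n")
  invisible(x)
}
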