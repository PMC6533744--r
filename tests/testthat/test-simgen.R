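# Synthetic genome pair, in-silico digestion, size selection, read simulation.

test_that("sim_config enforces its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(select_min = 700, select_max = 600), "select_min")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(genome_length = 5000, n_w_regions = 3,
                          w_region_length = 2000), "planted W length")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(enzyme_a_site = "GAAXTC"), "A/C/G/T")
})

test_that("build_genomes plants discoverable female-limited regions", {
  cfg0 <- sim_config(genome_length = 20000L, n_w_regions = 0L, rng_seed = 3)
  gp0 <- build_genomes(cfg0)
  expect_identical(gp0$female_genome, gp0$male_genome)

  cfg <- sim_config(genome_length = 100000L, n_w_regions = 3L,
                    w_region_length = 2000L, rng_seed = 7)
  gp <- build_genomes(cfg)
  gp2 <- build_genomes(cfg)
  expect_identical(gp, gp2)  # byte-identical for a fixed seed
  expect_identical(gp$male_genome, gp$shared_sequence)
  expect_equal(nrow(gp$w_regions), 3L)
  for (i in seq_len(3)) {
    reg <- gp$w_regions$region_seq[i]
    # naive substring scan: planted sequence present in female, absent in male
    expect_true(grepl(reg, gp$female_genome, fixed = TRUE))
    expect_false(grepl(reg, gp$male_genome, fixed = TRUE))
    # truth coordinates point at the guaranteed fragment
    fs <- gp$w_regions$fragment_start[i]
    fe <- gp$w_regions$fragment_end[i]
    expect_identical(substr(gp$female_genome, fs + 1L, fe),
                     gp$w_regions$fragment_seq[i])
    # discoverable: at least one site of each enzyme inside the region
    expect_gte(length(scan_motif(reg, cfg$enzyme_a_site)), 1L)
    expect_gte(length(scan_motif(reg, cfg$enzyme_b_site)), 1L)
  }
})

test_that("digest_genome returns exactly the oracle's A/B-flanked fragments", {
  expect_equal(nrow(digest_genome("ACGTACGTCATGACGTCATGACGT")), 0L)
  expect_error(digest_genome("ACGT", site_a = "GAAXTC"), "A/C/G/T")

  # hand-built 60-nt sequence: one EcoRI site, one downstream NlaIII site
  seq60 <- paste0(strrep("A", 10), "GAATTC", strrep("TC", 10), "CATG",
                  strrep("T", 20))
  fr <- digest_genome(seq60)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 11L)   # cut at G^AATTC
  expect_equal(fr$end, 40L)     # cut after CATG^
  expect_identical(fr$sequence, paste0("AATTC", strrep("TC", 10), "CATG"))
  expect_identical(fr[names(fr)], oracle_digest(seq60)[names(fr)])

  for (seed in 1:10) {
    set.seed(seed)
    s <- rand_dna(50000)
    got <- digest_genome(s)
    want <- oracle_digest(s)
    expect_identical(got[order(got$start), ], want[order(want$start), ],
                     info = paste("seed", seed))
  }
})

test_that("size selection keeps the inclusive gel window", {
  cfg <- sim_config()
  frag <- function(len) data.frame(start = 0L, end = len,
                                   sequence = strrep("A", len),
                                   flank_left = "A", flank_right = "B",
                                   stringsAsFactors = FALSE)
  expect_equal(nrow(size_select(frag(325), cfg)), 1L)  # 325 + 75 = 400
  expect_equal(nrow(size_select(frag(525), cfg)), 1L)  # upper bound 600
  expect_equal(nrow(size_select(frag(324), cfg)), 0L)
  expect_equal(nrow(size_select(frag(526), cfg)), 0L)  # 601 > 600

  set.seed(5)
  lens <- sample(200:700, 300, replace = TRUE)
  frags <- do.call(rbind, lapply(lens, frag))
  got <- size_select(frags, cfg)
  want <- frags[lens + 75 >= 400 & lens + 75 <= 600, , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("error-free reads are exact fragment-template prefixes", {
  pop <- small_population(seed = 19, genome_length = 50000L,
                          n_w_regions = 2L)
  reads <- simulate_reads(pop$frags, pop$inds, pop$cfg)
  expect_identical(reads, simulate_reads(pop$frags, pop$inds, pop$cfg))
  tmpl <- list(female = fragment_template(pop$frags$female, pop$cfg),
               male = fragment_template(pop$frags$male, pop$cfg))
  for (i in seq_len(nrow(reads$r1))) {
    ind <- reads$r1$individual_id[i]
    mid <- pop$inds$mid[pop$inds$individual_id == ind]
    sex <- pop$inds$sex[pop$inds$individual_id == ind]
    expect_true(startsWith(reads$r1$bases[i], mid))
    body <- substring(reads$r1$bases[i], nchar(mid) + 1L)
    expect_true(any(startsWith(tmpl[[sex]], body)))
  }
})

test_that("read counts follow the Poisson depth law", {
  cfg <- sim_config(genome_length = 100000L, n_w_regions = 0L,
                    mean_depth = 5, rng_seed = 23)
  set.seed(1)
  frags <- data.frame(start = 0L, end = 400L,
                      sequence = replicate(1000, paste0("AATTC",
                                                        rand_dna(391),
                                                        "CATG")),
                      flank_left = "A", flank_right = "B",
                      stringsAsFactors = FALSE)
  one <- data.frame(individual_id = "I1", sex = "female", mid = "ACGT",
                    stringsAsFactors = FALSE)
  reads <- simulate_reads(frags, one, cfg)
  # total ~ Poisson(5000): within 3 standard deviations
  expect_lt(abs(nrow(reads$r1) - 5000), 3 * sqrt(5000))
})

test_that("demultiplexing recovers the emitted per-individual counts", {
  pop <- small_population(seed = 31, genome_length = 50000L,
                          n_w_regions = 1L)
  reads <- simulate_reads(pop$frags, pop$inds, pop$cfg)
  truth <- table(reads$r1$individual_id)
  dmx <- demultiplex(reads$r1[, c("read_id", "bases", "qualities")],
                     pop$inds)
  expect_equal(nrow(dmx$unassigned), 0L)
  got <- table(dmx$assigned$individual_id)
  expect_equal(as.vector(got[names(truth)]), as.vector(truth))
  expect_error(simulate_reads(pop$frags,
                              transform(pop$inds, mid = "AAAA"), pop$cfg),
               "duplicate MIDs")
})

test_that("every planted W region yields a female-only tag at depth 5", {
  for (seed in c(42L, 1042L)) {
    pop <- small_population(seed = seed)
    reads <- simulate_reads(pop$frags, pop$inds, pop$cfg)
    sex_of <- setNames(pop$inds$sex, pop$inds$individual_id)
    mid_of <- setNames(pop$inds$mid, pop$inds$individual_id)
    mids <- mid_of[reads$r1$individual_id]
    tags <- canonical_seq(substr(substring(reads$r1$bases, nchar(mids) + 1L),
                                 1L, 110L))
    female_tags <- tags[sex_of[reads$r1$individual_id] == "female"]
    male_tags <- tags[sex_of[reads$r1$individual_id] == "male"]
    for (tag in planted_tags(pop)) {
      expect_true(tag %in% female_tags)
      expect_false(tag %in% male_tags)
    }
  }
})
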