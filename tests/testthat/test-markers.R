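# In-silico PCR, panel genotyping, genetic sex calls, reversal detection.

test_that("in-silico PCR finds the constructed amplicon of a real pair", {
  panel <- adav_primer_panel()
  p225 <- panel[panel$name == "adf225", ]
  set.seed(41)
  template <- paste0(p225$forward_seq, rand_dna(122),
                     dna_revcomp(p225$reverse_seq))
  hits <- insilico_pcr(p225, template, max_product_bp = 500)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, 162L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 162L)

  # primers absent from an unrelated template
  expect_equal(nrow(insilico_pcr(p225, rand_dna(500))), 0L)
  short <- p225; short$forward_seq <- "ACGTACGTACGT"
  expect_error(insilico_pcr(short, template), "15 nt")
})

test_that("in-silico PCR equals the sliding-window oracle with mismatches", {
  set.seed(43)
  for (i in 1:10) {
    fwd <- rand_dna(20)
    rev <- rand_dna(20)
    mm <- i %% 3  # mismatch budgets 0, 1, 2
    plant_f <- fwd
    plant_r <- dna_revcomp(rev)
    if (mm > 0) {
      # mutate internal bases (never the 3'-anchored ends)
      substr(plant_f, 3, 2 + mm) <- strrep("A", mm)
      substr(plant_r, 10, 9 + mm) <- strrep("A", mm)
    }
    template <- paste0(rand_dna(50), plant_f, rand_dna(80), plant_r,
                       rand_dna(50))
    pair <- primer_pair("p", fwd, rev, expected_product_bp = 120)
    got <- insilico_pcr(pair, template, max_product_bp = 300,
                        max_primer_mismatches = mm)
    want <- oracle_pcr(fwd, rev, template, max_product = 300, max_mm = mm)
    expect_equal(got, want, info = paste("instance", i))
  }
})

test_that("a mismatched 3'-terminal base blocks amplification", {
  set.seed(44)
  fwd <- rand_dna(20)
  rev <- rand_dna(20)
  broken <- fwd
  substr(broken, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 20, 20))[1]
  template <- paste0(broken, rand_dna(100), dna_revcomp(rev))
  pair <- primer_pair("p", fwd, rev, expected_product_bp = 140)
  # one mismatch allowed, but it sits on the forward 3' base -> no product
  expect_equal(nrow(insilico_pcr(pair, template,
                                 max_primer_mismatches = 1)), 0L)
  # the same mismatch anywhere else is tolerated
  internal <- fwd
  substr(internal, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 5, 5))[1]
  template2 <- paste0(internal, rand_dna(100), dna_revcomp(rev))
  expect_equal(nrow(insilico_pcr(pair, template2,
                                 max_primer_mismatches = 1)), 1L)
})

test_that("panel genotyping separates carriers from non-carriers", {
  set.seed(45)
  marker <- paste0("AATTC", rand_dna(101), "CATG")  # a 110-nt tag
  panel <- markers_to_panel(data.frame(marker_id = "w1", sequence = marker,
                                       stringsAsFactors = FALSE))
  carrier <- paste0(rand_dna(300), marker, rand_dna(300))
  noncarrier <- rand_dna(700)
  templates <- list(F1 = carrier, F2 = carrier, M1 = noncarrier,
                    M2 = noncarrier)
  gm <- genotype_panel(templates, panel)
  expect_equal(unname(gm[, "w1"]), c(TRUE, TRUE, FALSE, FALSE))

  # empty panel -> zero-column matrix
  gm0 <- genotype_panel(templates, panel[0, ])
  expect_equal(dim(gm0), c(4L, 0L))

  # missing template: error entry, run continues
  expect_warning(gmNA <- genotype_panel(c(templates, list(X = character(0))),
                                        panel),
                 "missing template")
  expect_true(is.na(gmNA["X", "w1"]))
  expect_false(any(is.na(gmNA[names(templates), ])))
})

test_that("genetic sex calls follow the marker system and majority vote", {
  m1 <- matrix(c(TRUE, FALSE), ncol = 1,
               dimnames = list(c("a", "b"), "w1"))
  expect_equal(call_genetic_sex(m1, "ZW_female_marker"),
               c(a = "female", b = "male"))
  expect_equal(call_genetic_sex(m1, "XY_male_marker"),
               c(a = "male", b = "female"))
  expect_error(call_genetic_sex(m1, "WZ"), "arg")

  # two discordant markers tie -> indeterminate
  m2 <- matrix(c(TRUE, FALSE), nrow = 1, dimnames = list("a", c("w1", "w2")))
  expect_equal(unname(call_genetic_sex(m2, "ZW_female_marker")),
               "indeterminate")

  # validation fixture: 4 concordant markers, 48 individuals
  v <- adav_band_patterns("validation")
  gs <- call_genetic_sex(v$bands, "ZW_female_marker")
  expect_equal(unname(gs), unname(v$phenotype))
})

test_that("reversal detection reproduces the exposure-group outcomes", {
  ht <- adav_band_patterns("temperature")
  rep_ht <- detect_reversals(call_genetic_sex(ht$bands, "ZW_female_marker"),
                             ht$phenotype)
  expect_equal(rep_ht$counts[["female_to_male"]], 3L)
  expect_equal(rep_ht$counts[["male_to_female"]], 0L)
  expect_equal(sum(rep_ht$crosstab), 24L)

  e2 <- adav_band_patterns("estradiol")
  rep_e2 <- detect_reversals(call_genetic_sex(e2$bands, "ZW_female_marker"),
                             e2$phenotype)
  expect_equal(rep_e2$counts[["male_to_female"]], 13L)
  expect_equal(rep_e2$counts[["female_to_male"]], 0L)
  expect_equal(sum(rep_e2$crosstab), 23L)
  # cross-tab marginals equal the group sizes
  expect_equal(unname(rowSums(rep_e2$crosstab)), c(20L, 3L))

  # concordant population -> empty report
  gs <- setNames(c("female", "male"), c("i1", "i2"))
  rep0 <- detect_reversals(gs, gs)
  expect_equal(nrow(rep0$discordant), 0L)

  # invariant to individual ordering
  perm <- sample(names(e2$phenotype))
  rep_perm <- detect_reversals(
    call_genetic_sex(e2$bands[perm, , drop = FALSE], "ZW_female_marker"),
    e2$phenotype[perm])
  expect_equal(rep_perm$counts, rep_e2$counts)

  expect_error(detect_reversals(gs, setNames(gs, c("i1", "i3"))),
               "same individual ids")
})

test_that("discovered markers genotype their own population perfectly", {
  pop <- small_population(seed = 91, genome_length = 60000L,
                          n_w_regions = 2L)
  cats <- population_catalogs(pop)
  females <- pop$inds$individual_id[pop$inds$sex == "female"]
  males <- pop$inds$individual_id[pop$inds$sex == "male"]
  scr <- genome_filter(cross_sex_screen(cats[females], cats[males]),
                       pop$gp$male_genome)
  fm <- final_markers(scr)
  expect_gt(nrow(fm), 0L)
  panel <- markers_to_panel(fm)
  templates <- lapply(setNames(pop$inds$sex, pop$inds$individual_id),
                      function(s) if (s == "female") pop$gp$female_genome
                                  else pop$gp$male_genome)
  gs <- call_genetic_sex(genotype_panel(templates, panel),
                         "ZW_female_marker")
  truth <- setNames(pop$inds$sex, pop$inds$individual_id)
  rep_sim <- detect_reversals(gs, truth)
  expect_equal(nrow(rep_sim$discordant), 0L)
  expect_equal(unname(gs[names(truth)]), unname(truth))
})
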