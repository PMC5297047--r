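test_that("generate_reference is deterministic and honors length and GC", {
  spec <- synthetic_genome_spec(1, 100000, 0.5, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  ref1 <- generate_reference(spec, fasta = f1)
  ref2 <- generate_reference(spec, fasta = f2)
  expect_equal(Biostrings::width(ref1), 100000L)
  expect_identical(readLines(f1), readLines(f2))

  spec3 <- synthetic_genome_spec(1, 200000, 0.3, seed = 1)
  ref3 <- generate_reference(spec3)
  gc <- sum(Biostrings::letterFrequency(ref3, c("G", "C"))) / 200000
  expect_gte(gc, 0.28)
  expect_lte(gc, 0.32)

  expect_error(synthetic_genome_spec(0, 1e5, 0.4), "n_chroms")
  expect_error(synthetic_genome_spec(1, 100, 0.4), "chrom_length")
  expect_error(synthetic_genome_spec(1, 1e5, 1.2), "gc_fraction")
})

test_that("plant_variants places classes, regions and germline as stated", {
  w <- small_world()

  # germline_rate = 0 leaves no germline loci
  t0 <- plant_variants(w$ref, germline_rate = 0, n_somatic = 50, seed = 5)
  expect_equal(nrow(t0$germline), 0L)

  # all weight on C>T forces C>T (or its G>A strand image) everywhere
  w_ct <- c(0, 0, 1, 0, 0, 0)
  t1 <- plant_variants(w$ref, germline_rate = 0, n_somatic = 50,
                       spectrum_weights = w_ct, seed = 5)
  expect_true(all(t1$somatic$class == "C>T"))
  expect_true(all(paste0(t1$somatic$ref, ">", t1$somatic$alt) %in%
                    c("C>T", "G>A")))

  # realized class proportions track the weights at n = 2000
  ww <- c(0.1, 0.1, 0.6, 0.05, 0.1, 0.05)
  t2 <- plant_variants(w$ref, germline_rate = 0, n_somatic = 2000,
                       spectrum_weights = ww, seed = 6)
  prop <- table(factor(t2$somatic$class, levels = SBS_CLASSES)) / 2000
  expect_true(all(abs(as.numeric(prop) - ww / sum(ww)) <= 0.03))

  # truth invariants: disjoint germline/somatic, ref matches reference
  tr <- w$truth
  kg <- with(tr$germline, paste(chrom, pos))
  ks <- with(tr$somatic, paste(chrom, pos))
  expect_length(intersect(kg, ks), 0)
  idx <- sample(nrow(tr$somatic), 50)
  seq1 <- as.character(tr$reference[["chr1"]])
  expect_identical(substring(seq1, tr$somatic$pos[idx], tr$somatic$pos[idx]),
                   tr$somatic$ref[idx])
  expect_true(all(tr$somatic$region %in%
                    c("exonic", "intronic", "intergenic")))

  # capacity error when the genome cannot host the request
  expect_error(plant_variants(w$ref, germline_rate = 0, n_somatic = 1e7,
                              seed = 1),
               "capacity|exceeds")
})

test_that("plant_variants determinism: same seed, same truth", {
  w <- small_world()
  a <- plant_variants(w$ref, n_somatic = 100, seed = 42)
  b <- plant_variants(w$ref, n_somatic = 100, seed = 42)
  expect_identical(a$somatic, b$somatic)
  expect_identical(a$germline, b$germline)
})

test_that("simulate_caller respects sensitivity extremes and labels", {
  w <- small_world()
  tr <- w$truth

  m_all <- caller_model("perfect", sensitivity = 1,
                        false_positive_rate_per_mb = 0,
                        score_informative = TRUE, seed = 3,
                        germline_call_prob = 0)
  calls <- simulate_caller(tr, m_all)
  expect_setequal(with(calls, paste(chrom, pos, ref, alt)),
                  with(tr$somatic, paste(chrom, pos, ref, alt)))
  expect_true(all(calls$label == "somatic_true"))

  m_none <- caller_model("blind", sensitivity = 0,
                         false_positive_rate_per_mb = 100,
                         score_informative = TRUE, seed = 3,
                         germline_call_prob = 0.5)
  fp <- simulate_caller(tr, m_none)
  expect_true(all(fp$label %in% c("germline_contamination", "error")))

  # truth labels partition every callset
  cs <- dual_callers(tr)
  for (calls in cs) {
    expect_true(all(calls$label %in%
                      c("somatic_true", "germline_contamination", "error")))
  }

  # informative scores separate true from false calls (rank AUC > 0.8)
  big <- plant_variants(w$ref, germline_rate = 0.02, n_somatic = 600,
                        seed = 9, confusable_fraction = 0.9)
  m_inf <- caller_model("informative", 0.9, 500, TRUE, seed = 10,
                        germline_call_prob = 0.9)
  ci <- simulate_caller(big, m_inf)
  expect_gt(sum(ci$label != "somatic_true"), 100)
  expect_gt(brute_auc(ci$quality, ci$label == "somatic_true"), 0.8)

  # uninformative scores do not
  m_unf <- caller_model("flat", 0.9, 500, FALSE, seed = 10,
                        germline_call_prob = 0.9)
  cu <- simulate_caller(big, m_unf)
  expect_lt(abs(brute_auc(cu$quality, cu$label == "somatic_true") - 0.5),
            0.1)
})

test_that("simulate_validation_reads draws around the planted fractions", {
  w <- small_world()
  tr <- w$truth
  som <- tr$somatic[1:50, ]
  rc <- simulate_validation_reads(som, tr, depth = 1000, error_rate = 0,
                                  seed = 4)
  expect_true(all(rc$true_class == "somatic"))
  expect_true(all(rc$n_alt == 0))        # error-free normal stays clean
  taf <- rc$t_alt / (rc$t_alt + rc$t_ref)
  expect_true(all(abs(taf - tr$clonal_fraction) < 0.1))

  germ <- tr$germline[1:50, ]
  rg <- simulate_validation_reads(germ, tr, depth = 1000,
                                  error_rate = 0.002, seed = 5)
  expect_true(all(rg$true_class == "germline"))
  taf <- rg$t_alt / (rg$t_alt + rg$t_ref)
  naf <- rg$n_alt / (rg$n_alt + rg$n_ref)
  expect_true(all(taf > 0.4 & taf < 0.6))
  expect_true(all(naf > 0.4 & naf < 0.6))

  err <- data.frame(chrom = "chr1", pos = c(17L, 23L), ref = "A", alt = "T")
  re <- simulate_validation_reads(err, tr, depth = 1000,
                                  error_rate = 0.002, seed = 6)
  expect_true(all(re$true_class == "error"))
  expect_true(all(re$t_alt / (re$t_alt + re$t_ref) < 0.05))
})

test_that("simulate_cross_species_tables plants enrichment and mappings", {
  # enrichment 1 everywhere: frequencies agree in expectation
  null_t <- simulate_cross_species_tables(
    n_genes = 50, cohort_sizes = c(baseline = 5000, resistant = 5000),
    per_gene_enrichment = c(zgene0001 = 1), baseline_rate = 0.02,
    seed = 11, duplicate_fraction = 0)
  cf <- cohort_frequencies(null_t$mutations,
                           cohort_sizes = null_t$truth$cohort_sizes)
  wide <- reshape(cf[, c("gene", "cohort", "frequency")],
                  idvar = "gene", timevar = "cohort", direction = "wide")
  expect_lt(max(abs(wide$frequency.baseline - wide$frequency.resistant)),
            0.02)

  # pure 1:1 mapping: every mapped fish gene has exactly one candidate row
  o11 <- simulate_cross_species_tables(
    n_genes = 40, seed = 12,
    ortholog_fractions = c(one_to_one = 1, many_to_one = 0, unmapped = 0),
    multi_candidate_fraction = 0)
  expect_equal(anyDuplicated(o11$orthologs$fish_id), 0L)
  expect_equal(nrow(o11$orthologs), 40L)
  expect_equal(anyDuplicated(o11$orthologs$human_symbol), 0L)

  # baseline 2%, enrichment 3.5, n = 10,000 -> resistant frequency 6-8%
  big <- simulate_cross_species_tables(
    n_genes = 20, cohort_sizes = c(baseline = 10000, resistant = 10000),
    per_gene_enrichment = c(zgene0001 = 3.5), baseline_rate = 0.02,
    seed = 13, duplicate_fraction = 0)
  cf2 <- cohort_frequencies(big$mutations, genes = "zgene0001",
                            cohort_sizes = big$truth$cohort_sizes)
  fr <- cf2$frequency[cf2$cohort == "resistant"]
  expect_gte(fr, 0.06)
  expect_lte(fr, 0.08)
})
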