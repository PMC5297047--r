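test_that("extrapolation floors and the per-Mb display truncates", {
  expect_identical(extrapolate_true_count(13811, 0.23), 3176L)
  expect_identical(extrapolate_true_count(100, 1.0), 100L)
  expect_identical(extrapolate_true_count(1000, 0.38), 380L)
  expect_error(extrapolate_true_count(-1, 0.5), "n_called")
  expect_error(extrapolate_true_count(10, 1.5), "validation_rate")

  # floor linearity: doubling calls doubles the estimate up to the floor
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:20000, 1); r <- runif(1)
    e1 <- extrapolate_true_count(n, r)
    e2 <- extrapolate_true_count(2 * n, r)
    expect_true(e2 %in% c(2 * e1, 2 * e1 + 1))
  }

  expect_equal(format_rate_per_mb(rate_per_mb(3176, 1412464843)), "2.24")
  expect_equal(format_rate_per_mb(rate_per_mb(10, 1e6)), "10.00")
  expect_error(rate_per_mb(10, 0), "genome_size")

  est <- mutation_rate_estimate(13811, 0.23)
  expect_identical(est$expected_true, 3176L)
  expect_identical(est$rate_per_mb_display, "2.24")
  expect_gt(est$rate_per_mb, 2.24)  # full precision retained (2.2485...)
})

test_that("spectrum strand-normalizes classes and contexts", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
  # C>T at pos 3, context A[C>T]G
  v1 <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  s1 <- substitution_spectrum(v1, ref)
  expect_equal(s1$class_counts[["C>T"]], 1L)
  expect_equal(s1$context_counts[["A[C>T]G"]], 1L)
  # G>A at pos 4 (triplet CGT): reverse complement is also A[C>T]G
  v2 <- data.frame(chrom = "chr1", pos = 4, ref = "G", alt = "A")
  s2 <- substitution_spectrum(v2, ref)
  expect_equal(s2$class_counts[["C>T"]], 1L)
  expect_equal(s2$context_counts[["A[C>T]G"]], 1L)

  # REF mismatch names the locus
  bad <- data.frame(chrom = "chr1", pos = 3, ref = "G", alt = "A")
  expect_error(substitution_spectrum(bad, ref), "chr1:3")

  # sequence-end variants counted in classes, excluded from contexts
  vend <- data.frame(chrom = "chr1", pos = c(1, 6), ref = c("A", "T"),
                     alt = c("G", "C"))
  send <- substitution_spectrum(vend, ref)
  expect_equal(send$n_total, 2L)
  expect_equal(send$n_context_excluded, 2L)
  expect_equal(sum(send$context_counts), 0L)
})

test_that("planted spectra are recovered exactly from truth", {
  w <- small_world(seed = 501, n_somatic = 300)
  tr <- w$truth
  sp <- substitution_spectrum(tr$somatic, tr$reference)
  planted <- table(factor(tr$somatic$class, levels = SBS_CLASSES))
  expect_equal(as.integer(sp$class_counts), as.integer(planted))
  # conservation: contexts + end-excluded = classes
  expect_equal(sum(sp$context_counts) + sp$n_context_excluded, sp$n_total)
  expect_equal(sum(sp$class_counts), sp$n_total)
})

test_that("the pyrimidine-normalized spectrum is strand-involutive", {
  w <- small_world(seed = 502, n_somatic = 200)
  tr <- w$truth
  sp <- substitution_spectrum(tr$somatic, tr$reference)
  flipped_ref <- Biostrings::reverseComplement(tr$reference)
  names(flipped_ref) <- names(tr$reference)
  len <- Biostrings::width(tr$reference)[1]
  flipped <- within(tr$somatic, {
    pos <- len - pos + 1L
    tmp_ref <- ref
    ref <- unname(c(A = "T", C = "G", G = "C", T = "A")[ref])
    alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[alt])
    rm(tmp_ref)
  })
  sp2 <- substitution_spectrum(flipped, flipped_ref)
  expect_identical(sp$class_counts, sp2$class_counts)
  expect_identical(sp$context_counts, sp2$context_counts)
})

test_that("dipyrimidine report uses both denominators", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ATCAGTCGATCCA"))
  # TCA at 2-4, TCG at 6-8, TCC at 10-12; mutate the central C of each
  v <- data.frame(chrom = "chr1", pos = c(3, 7, 11),
                  ref = "C", alt = "T")
  sp <- substitution_spectrum(v, ref)
  rep <- dipyrimidine_report(sp)
  expect_equal(rep$count[rep$context == "TCA"], 1L)
  expect_equal(rep$frac_of_all[rep$context == "TCA"], 1 / 3)
  expect_equal(rep$frac_of_ct[rep$context == "TCA"], 1 / 3)
  expect_equal(rep$frac_of_all[rep$context == "dipyrimidine"], 1)

  # all mutations at T[C>T]A
  v2 <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  r2 <- dipyrimidine_report(substitution_spectrum(v2, ref))
  expect_equal(r2$frac_of_all[r2$context == "TCA"], 1)

  # no C>T mutations at all
  v3 <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "A")
  r3 <- dipyrimidine_report(substitution_spectrum(v3, ref))
  expect_true(all(r3$frac_of_all == 0))
})

test_that("region breakdown handles BED conventions and matches truth", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t100\tg1\t0\t+", bed)  # 0-based [99,100) = pos 100
  v <- data.frame(chrom = "chr1", pos = c(100, 101, 5000))
  rb <- region_breakdown(v, bed)
  expect_equal(rb$labels, c("exonic", "intergenic", "intergenic"))
  expect_equal(sum(rb$fractions), 1)

  w <- small_world(seed = 503, n_somatic = 500)
  rb2 <- region_breakdown(w$truth$somatic, w$truth$gene_model)
  expect_identical(rb2$labels, w$truth$somatic$region)

  # BED12 round trip preserves exon/intron structure
  bed12 <- withr::local_tempfile(fileext = ".bed")
  write_gene_model_bed(w$truth$gene_model, bed12)
  rb3 <- region_breakdown(w$truth$somatic, bed12)
  expect_identical(rb3$labels, rb2$labels)
})

test_that("signature similarity ranks by cosine with stable ties", {
  sig <- random_signature_matrix(4, seed = 9)
  expect_equal(colSums(sig), rep(1, 4), ignore_attr = TRUE)

  # spectrum equal to a signature ranks it first at cosine 1
  counts <- round(sig[, 2] * 10000)
  r <- signature_similarity(counts, sig)
  expect_equal(r$signature[1], "signature_2")
  expect_gt(r$cosine[1], 0.999)

  # orthogonal one-context signature scores 0
  one <- matrix(0, 96, 1, dimnames = list(sbs_context_levels(), "only"))
  one["A[C>A]A", 1] <- 1
  v <- setNames(rep(1, 96), sbs_context_levels())
  v["A[C>A]A"] <- 0
  expect_equal(signature_similarity(v, one)$cosine, 0)

  # 0.9/0.1 mixture ranks the dominant signature first
  mix <- 0.9 * sig[, 1] + 0.1 * sig[, 3]
  r2 <- signature_similarity(round(mix * 1e5), sig)
  expect_equal(r2$signature[1], "signature_1")

  expect_error(signature_similarity(rep(0, 96), sig), "empty")

  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, f)
  sig2 <- read_signature_tsv(f)
  r3 <- signature_similarity(counts, f)
  expect_equal(r3$signature[1], "signature_2")
  expect_equal(unname(sig2), unname(sig), tolerance = 1e-8)
})
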