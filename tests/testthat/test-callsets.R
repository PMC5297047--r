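vcf_lines <- function(body) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Genotype\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"),
    body)
}

test_that("load_calls keeps SNVs, splits multi-allelics, drops the rest", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tC\t12.5\tPASS\t.\tGT:AD\t0/1:20,10\t0/0:30,0",
    "chr1\t200\t.\tC\tG\t9.0\tPASS\t.\tGT:AD\t0/1:18,9\t0/0:28,1",
    "chr1\t300\t.\tT\tA\t7.5\tPASS\t.\tGT:AD\t0/1:22,8\t0/0:31,0",
    "chr1\t400\t.\tTA\tT\t5.0\tPASS\t.\tGT:AD\t0/1:20,5\t0/0:30,0",
    "chr1\t500\t.\tA\tC,T\t6.0\tPASS\t.\tGT:AD\t1/2:10,5,5\t0/0:30,0,0"
  )), f)
  expect_message(calls <- load_calls(f, "toolX"), "dropped 1")
  expect_equal(nrow(calls), 5L)  # 3 SNVs + 2 from the multi-allelic split
  expect_equal(sum(calls$pos == 500), 2L)
  expect_setequal(calls$alt[calls$pos == 500], c("C", "T"))
  expect_true(all(calls$caller == "toolX"))
  expect_equal(calls$quality[calls$pos == 100], 12.5)
  expect_equal(calls$t_alt[calls$pos == 100], 10L)
  expect_equal(calls$n_ref[calls$pos == 100], 30L)

  # empty body
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(character(0)), f2)
  expect_equal(nrow(load_calls(f2, "toolX")), 0L)

  # malformed input is reported as a parse failure naming the file
  f3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all", "chr1\t10"), f3)
  expect_error(load_calls(f3, "toolX"), "parse|Failed")
})

test_that("load_calls round-trips the simulator's VCF output", {
  w <- small_world(n_somatic = 150)
  m <- caller_model("sim", 0.9, 200, TRUE, seed = 8)
  f <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulate_caller(w$truth, m, vcf = f)
  got <- load_calls(f, "sim")
  expect_equal(nrow(got), nrow(sim))
  expect_setequal(with(got, paste(chrom, pos, ref, alt)),
                  with(sim, paste(chrom, pos, ref, alt)))
  expect_equal(got$t_alt[order(got$pos)], sim$t_alt[order(sim$pos)])
})

test_that("consensus obeys set algebra", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, ref = "C",
                                 alt = "T", quality = 1)
  # identical callsets
  r <- consensus(list(a = mk(1:10), b = mk(1:10)))
  expect_equal(r$intersection_count, 10L)
  expect_equal(r$union_count, 10L)
  # disjoint
  r <- consensus(list(a = mk(1:10), b = mk(11:15)))
  expect_equal(r$intersection_count, 0L)
  expect_equal(r$union_count, 15L)
  # partial overlap, by hand: {1,2,3} vs {2,3,4}
  r <- consensus(list(a = mk(1:3), b = mk(2:4)))
  expect_equal(r$intersection_count, 2L)
  expect_equal(r$union_count, 4L)
  # single caller is a usage error
  expect_error(consensus(list(a = mk(1:3))), "two")

  # chr-prefix dialects are matched
  a <- data.frame(chrom = "chr1", pos = 1:5, ref = "C", alt = "T")
  b <- data.frame(chrom = "1", pos = 3:7, ref = "C", alt = "T")
  r <- consensus(list(a = a, b = b))
  expect_equal(r$intersection_count, 3L)

  # property: |A u B| = |A| + |B| - |A n B| over random sets
  set.seed(99)
  for (i in 1:20) {
    a <- mk(sample(1:60, sample(5:40, 1)))
    b <- mk(sample(1:60, sample(5:40, 1)))
    r <- consensus(list(a = a, b = b))
    expect_equal(r$union_count,
                 sum(r$per_caller_counts) - r$intersection_count)
    expect_true(all(r$intersection_keys %in%
                      with(a, paste("1", pos, "C", "T", sep = ":"))))
  }
})

test_that("quartile stratification partitions calls on score percentiles", {
  mk <- function(q) data.frame(chrom = "chr1", pos = seq_along(q),
                               ref = "C", alt = "T", quality = q)
  st <- quartile_stratify(mk(1:8))
  expect_equal(vapply(st, nrow, integer(1)), c(Q1 = 2L, Q2 = 2L,
                                               Q3 = 2L, Q4 = 2L))
  # boundary check against a brute-force percentile computation
  calls <- mk(1:100)
  st <- quartile_stratify(calls)
  q25 <- stats::quantile(calls$quality, 0.25)
  expect_true(all(st$Q1$quality <= q25))
  expect_true(all(st$Q2$quality > q25))
  # partition: union of bins is the callset, bins disjoint
  pooled <- do.call(rbind, st[1:4])
  expect_setequal(pooled$pos, calls$pos)
  expect_equal(nrow(pooled), nrow(calls))

  expect_warning(st0 <- quartile_stratify(mk(rep(3, 6))), "identical")
  expect_equal(nrow(st0$Q1), 6L)
  expect_error(quartile_stratify(mk(1:3)), "4")
})

test_that("build_panel draws the designed strata deterministically", {
  w <- small_world(n_somatic = 600, chrom_length = 100000)
  cs <- dual_callers(w$truth)
  rep <- consensus(cs)
  st <- lapply(cs, quartile_stratify)

  des <- panel_design(40, 20, 5)
  p1 <- build_panel(rep, st, des, seed = 77)
  p2 <- build_panel(rep, st, des, seed = 77)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 80L)
  expect_equal(sum(p1$source == "overlap"), 40L)
  expect_equal(sum(p1$source == "mutectish-unique"), 20L)

  # membership invariants
  expect_true(all(p1$key[p1$source == "overlap"] %in%
                    rep$intersection_keys))
  expect_false(any(p1$key[p1$source != "overlap"] %in%
                     rep$intersection_keys))
  expect_equal(anyDuplicated(p1$key), 0L)

  # empty design, empty panel
  p0 <- build_panel(rep, st, panel_design(0, 0, 0), seed = 1)
  expect_equal(nrow(p0), 0L)

  # an infeasible stratum is named in the error
  expect_error(
    build_panel(rep, st, panel_design(1e5, 20, 5), seed = 1),
    "overlap")
  expect_error(
    build_panel(rep, st, panel_design(10, 1e5, 5), seed = 1),
    "quartile")

  # per-quartile mode draws 4 x n_per_quartile per caller
  pq <- build_panel(rep, st, panel_design(0, 0, 5, mode = "per_quartile"),
                    seed = 3)
  expect_lte(nrow(pq), 40L)   # duplicates across callers collapse
  expect_gte(nrow(pq), 20L)
  expect_true(all(table(pq$source[pq$source != "overlap"]) <= 20))
})
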