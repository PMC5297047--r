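#' Simulate deep orthogonal-validation readcounts at candidate loci
#'
#' Emulates a pooled deep-amplicon (MiSeq-style) validation run over a set
#' of candidate loci. Per locus, tumor and normal depths are drawn Poisson
#' around `depth` and alt counts are binomial with a success probability set
#' by the locus' true identity: somatic loci use the planted clonal fraction
#' in tumor and the sequencing error rate in normal; germline loci are
#' heterozygous (0.5) in both; all other loci (caller errors) see only
#' sequencing error in both samples.
#'
#' @param loci data frame with columns chrom, pos, ref, alt (e.g. a
#'   validation panel or a callset).
#' @param truth a `truth_set` from [plant_variants()].
#' @param depth mean per-sample depth at each locus.
#' @param error_rate per-base sequencing error rate.
#' @param seed integer seed.
#' @param tsv optional path; when given, a readcount table with header
#'   `chrom pos ref alt t_ref t_alt n_ref n_alt` is written.
#' @return data frame with the readcount columns plus a hidden-truth
#'   `true_class` column (somatic / germline / error) for testing.
#' @export
simulate_validation_reads <- function(loci, truth, depth = 500L,
                                      error_rate = 0.002, seed = 1L,
                                      tsv = NULL) {
  stopifnot(inherits(truth, "truth_set"), depth >= 1,
            error_rate >= 0, error_rate < 1)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  keys <- with(loci, variant_key(chrom, pos, ref, alt))
  som_keys <- with(truth$somatic, variant_key(chrom, pos, ref, alt))
  germ_keys <- with(truth$germline, variant_key(chrom, pos, ref, alt))
  true_class <- ifelse(keys %in% som_keys, "somatic",
                       ifelse(keys %in% germ_keys, "germline", "error"))
  n <- nrow(loci)
  with_seed(seed, {
    t_af <- ifelse(true_class == "somatic", truth$clonal_fraction,
                   ifelse(true_class == "germline", 0.5, error_rate))
    n_af <- ifelse(true_class == "germline", 0.5, error_rate)
    t_dp <- pmax(1L, stats::rpois(n, depth))
    n_dp <- pmax(1L, stats::rpois(n, depth))
    t_alt <- stats::rbinom(n, t_dp, t_af)
    n_alt <- stats::rbinom(n, n_dp, n_af)
    out <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
                      alt = loci$alt,
                      t_ref = t_dp - t_alt, t_alt = t_alt,
                      n_ref = n_dp - n_alt, n_alt = n_alt,
                      true_class = true_class, stringsAsFactors = FALSE)
    if (!is.null(tsv)) {
      write_tsv(out[, c("chrom", "pos", "ref", "alt",
                        "t_ref", "t_alt", "n_ref", "n_alt")], tsv)
    }
    out
  })
}
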