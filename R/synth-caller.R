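#' Describe a simulated somatic variant caller
#'
#' Encodes the behaviours that matter downstream: how many true somatic
#' variants the caller finds (`sensitivity`), how many spurious calls it
#' makes (germline miscalls plus random error calls at
#' `false_positive_rate_per_mb`), and whether its quality score carries
#' information about call correctness. With `score_informative = TRUE`,
#' true-call scores are drawn from a normal distribution shifted +1.5
#' standard deviations above false-call scores (a MuTect-like score); with
#' `FALSE`, true and false calls share one score distribution (a
#' Shimmer-like score whose ROC curve hugs the diagonal).
#'
#' @param name caller name, stored in the emitted calls.
#' @param sensitivity probability that each true somatic locus is called.
#' @param false_positive_rate_per_mb expected random-error calls per Mb
#'   (loci that are neither somatic nor germline in truth).
#' @param score_informative logical; see above.
#' @param seed integer seed.
#' @param germline_call_prob probability that each *confusable* germline
#'   locus (see [plant_variants()]) is miscalled as somatic. Confusable
#'   status lives on the locus, so two independent callers miscall largely
#'   the same germline SNPs — the dominant shared false-positive mode.
#' @return An object of class `caller_model`.
#' @export
caller_model <- function(name, sensitivity = 0.9,
                         false_positive_rate_per_mb = 0,
                         score_informative = TRUE, seed = 1L,
                         germline_call_prob = 0.9) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            false_positive_rate_per_mb >= 0,
            germline_call_prob >= 0, germline_call_prob <= 1,
            is.logical(score_informative))
  structure(list(name = as.character(name), sensitivity = sensitivity,
                 false_positive_rate_per_mb = false_positive_rate_per_mb,
                 score_informative = score_informative,
                 seed = as.integer(seed),
                 germline_call_prob = germline_call_prob),
            class = "caller_model")
}

#' Simulate a somatic caller run against a planted truth set
#'
#' Emits each true somatic locus with probability `model$sensitivity`.
#' False positives come from two sources: confusable germline loci (each
#' emitted with probability `model$germline_call_prob`) and random error
#' loci drawn Poisson at `model$false_positive_rate_per_mb`. Every emitted
#' record carries a truth label in `label` (and in the VCF `SIMCLASS` INFO
#' field): `somatic_true`, `germline_contamination` or `error`; the three
#' labels partition the callset.
#'
#' @param truth a `truth_set` from [plant_variants()].
#' @param model a [caller_model()].
#' @param vcf optional path; when given, calls are written as VCF 4.2 with
#'   the quality score in QUAL and tumor/normal allele depths in AD.
#' @param mean_depth mean simulated sequencing depth used for the cosmetic
#'   AD/DP fields (the discovery-run depth, not the validation depth).
#' @return data frame of calls with columns chrom, pos, ref, alt, caller,
#'   quality, t_ref, t_alt, n_ref, n_alt, label.
#' @export
simulate_caller <- function(truth, model, vcf = NULL, mean_depth = 40) {
  stopifnot(inherits(truth, "truth_set"), inherits(model, "caller_model"))
  with_seed(model$seed, {
    som <- truth$somatic
    keep <- stats::runif(nrow(som)) < model$sensitivity
    true_calls <- som[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    true_calls$label <- rep("somatic_true", nrow(true_calls))

    gl <- truth$germline[truth$germline$confusable, , drop = FALSE]
    keep_g <- stats::runif(nrow(gl)) < model$germline_call_prob
    germ_calls <- gl[keep_g, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    germ_calls$label <- rep("germline_contamination", nrow(germ_calls))

    n_err <- stats::rpois(1L, model$false_positive_rate_per_mb *
                            truth$genome_size / 1e6)
    err_calls <- NULL
    if (n_err > 0) {
      lens <- Biostrings::width(truth$reference)
      names(lens) <- names(truth$reference)
      taken <- c(variant_key(som$chrom, som$pos, som$ref, som$alt),
                 with(truth$germline, variant_key(chrom, pos, ref, alt)))
      taken_pos <- paste(c(som$chrom, truth$germline$chrom),
                         c(som$pos, truth$germline$pos))
      ch <- sample(names(lens), n_err, replace = TRUE,
                   prob = lens / sum(lens))
      pos <- vapply(ch, function(c2) sample.int(lens[[c2]], 1L), integer(1))
      ok <- !(paste(ch, pos) %in% taken_pos) & !duplicated(paste(ch, pos))
      ch <- ch[ok]; pos <- pos[ok]
      if (length(ch)) {
        refb <- mapply(function(c2, p)
          as.character(Biostrings::subseq(truth$reference[[c2]], p, p)),
          ch, pos, USE.NAMES = FALSE)
        alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
        err_calls <- data.frame(chrom = ch, pos = pos, ref = refb,
                                alt = alt, label = "error",
                                stringsAsFactors = FALSE)
      }
    }

    calls <- rbind(true_calls, germ_calls, err_calls)
    if (is.null(calls) || nrow(calls) == 0L) {
      calls <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          label = character(), stringsAsFactors = FALSE)
    }
    n <- nrow(calls)
    is_true <- calls$label == "somatic_true"

    # quality scores: informative = +1.5 sd shift for true calls
    if (model$score_informative) {
      calls$quality <- stats::rnorm(n, mean = ifelse(is_true, 6.5, 5), sd = 1)
    } else {
      calls$quality <- stats::rnorm(n, mean = 5, sd = 1)
    }

    # cosmetic discovery-run depths
    t_dp <- pmax(1L, stats::rpois(n, mean_depth))
    n_dp <- pmax(1L, stats::rpois(n, mean_depth))
    t_af <- ifelse(is_true, truth$clonal_fraction,
                   ifelse(calls$label == "germline_contamination", 0.5, 0.1))
    n_af <- ifelse(calls$label == "germline_contamination", 0.5, 0.001)
    calls$t_alt <- stats::rbinom(n, t_dp, t_af)
    calls$t_ref <- t_dp - calls$t_alt
    calls$n_alt <- stats::rbinom(n, n_dp, n_af)
    calls$n_ref <- n_dp - calls$n_alt
    calls$caller <- model$name
    calls <- calls[order(calls$chrom, calls$pos),
                   c("chrom", "pos", "ref", "alt", "caller", "quality",
                     "t_ref", "t_alt", "n_ref", "n_alt", "label")]
    rownames(calls) <- NULL
    if (!is.null(vcf)) {
      write_calls_vcf(calls, vcf, reference = truth$reference)
    }
    calls
  })
}

#' Write somatic calls as a VCF 4.2 file
#'
#' Emits a minimal tumor/normal VCF: QUAL holds the caller quality score,
#' the TUMOR and NORMAL sample columns carry GT:AD:DP, and (for simulated
#' calls) the truth label is recorded in the `SIMCLASS` INFO field.
#'
#' @param calls data frame as returned by [simulate_caller()] (the `label`
#'   column is optional).
#' @param path output path.
#' @param reference optional `DNAStringSet` used to write contig headers.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=xspec-simulator")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          Biostrings::width(reference)))
  }
  hdr <- c(hdr,
           paste0("##INFO=<ID=SIMCLASS,Number=1,Type=String,",
                  "Description=\"Simulation truth label\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  info <- if ("label" %in% names(calls)) {
    paste0("SIMCLASS=", calls$label)
  } else {
    rep(".", nrow(calls))
  }
  body <- character(0)
  if (nrow(calls) > 0) {
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  sprintf("%.4f", calls$quality), "PASS", info, "GT:AD:DP",
                  sprintf("0/1:%d,%d:%d", calls$t_ref, calls$t_alt,
                          calls$t_ref + calls$t_alt),
                  sprintf("0/0:%d,%d:%d", calls$n_ref, calls$n_alt,
                          calls$n_ref + calls$n_alt),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
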