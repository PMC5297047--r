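#' Classify validation readcounts as SOMATIC, GERMLINE or FAIL
#'
#' Applies the allele-fraction cutoffs used for orthogonal deep-sequencing
#' validation of candidate somatic calls:
#' \itemize{
#'   \item SOMATIC (validated): tumor AF >= `tumor_af_min` and
#'     normal AF < `normal_af_max`;
#'   \item GERMLINE (not validated): tumor AF >= `tumor_af_min` and
#'     normal AF >= `normal_af_max`;
#'   \item FAIL (not validated): tumor AF < `tumor_af_min`.
#' }
#' Allele fractions are computed as `alt / (ref + alt)` per sample; loci
#' with zero depth in either sample are flagged indeterminate (`NA`
#' verdict), excluded from rates, and counted in a message.
#'
#' @param readcounts data frame with columns t_ref, t_alt, n_ref, n_alt
#'   (plus any identifier columns, which are carried through), or a path to
#'   such a TSV.
#' @param tumor_af_min minimum tumor allele fraction (default 0.05, i.e.
#'   5%).
#' @param normal_af_max normal allele fraction at or above which a
#'   validated-looking locus is called germline (default 0.02, i.e. 2%).
#' @return the input with added columns `tumor_af`, `normal_af`, `verdict`
#'   (factor SOMATIC/GERMLINE/FAIL, `NA` when indeterminate).
#' @export
classify_validation <- function(readcounts, tumor_af_min = 0.05,
                                normal_af_max = 0.02) {
  if (is.character(readcounts) && length(readcounts) == 1L) {
    readcounts <- read_tsv_checked(readcounts,
                                   required = c("t_ref", "t_alt",
                                                "n_ref", "n_alt"))
  }
  need <- c("t_ref", "t_alt", "n_ref", "n_alt")
  if (!all(need %in% names(readcounts))) {
    stop("readcounts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(tumor_af_min >= 0, tumor_af_min <= 1,
            normal_af_max >= 0, normal_af_max <= 1)
  t_dp <- readcounts$t_ref + readcounts$t_alt
  n_dp <- readcounts$n_ref + readcounts$n_alt
  if (any(c(readcounts$t_ref, readcounts$t_alt,
            readcounts$n_ref, readcounts$n_alt) < 0, na.rm = TRUE)) {
    stop("negative read counts", call. = FALSE)
  }
  tumor_af <- ifelse(t_dp > 0, readcounts$t_alt / t_dp, NA_real_)
  normal_af <- ifelse(n_dp > 0, readcounts$n_alt / n_dp, NA_real_)
  verdict <- ifelse(tumor_af < tumor_af_min, "FAIL",
                    ifelse(normal_af < normal_af_max, "SOMATIC",
                           "GERMLINE"))
  indeterminate <- is.na(tumor_af) | is.na(normal_af)
  # a FAIL is decidable on tumor AF alone even with zero normal depth
  verdict[is.na(normal_af) & !is.na(tumor_af) &
            tumor_af < tumor_af_min] <- "FAIL"
  indeterminate <- indeterminate &
    !(is.na(normal_af) & !is.na(tumor_af) & tumor_af < tumor_af_min)
  verdict[indeterminate] <- NA_character_
  if (any(indeterminate)) {
    message("classify_validation: ", sum(indeterminate),
            " locus/loci with zero depth flagged indeterminate")
  }
  readcounts$tumor_af <- tumor_af
  readcounts$normal_af <- normal_af
  readcounts$verdict <- factor(verdict,
                               levels = c("SOMATIC", "GERMLINE", "FAIL"))
  readcounts
}

#' Validation rate per group with Wilson intervals
#'
#' The validation rate of a group is the fraction of its classified loci
#' with a SOMATIC verdict. Display percentages are rounded to the nearest
#' integer, except for groups of fewer than 50 loci where one decimal is
#' kept (e.g. 3/27 shows 11.1). Indeterminate (`NA`) verdicts are excluded.
#'
#' @param verdicts factor/character of verdicts, or a data frame with a
#'   `verdict` column.
#' @param group optional grouping vector (same length); when `NULL` a
#'   single group `all` is reported.
#' @param conf confidence level for the Wilson interval.
#' @return data frame with group, n_somatic, n_total, rate,
#'   percent_display, ci_lower, ci_upper.
#' @export
validation_rate <- function(verdicts, group = NULL, conf = 0.95) {
  if (is.data.frame(verdicts)) verdicts <- verdicts$verdict
  verdicts <- as.character(verdicts)
  if (is.null(group)) group <- rep("all", length(verdicts))
  stopifnot(length(group) == length(verdicts))
  all_groups <- unique(as.character(group))
  keep <- !is.na(verdicts)
  verdicts <- verdicts[keep]; group <- as.character(group)[keep]
  out <- lapply(all_groups, function(g) {
    v <- verdicts[group == g]
    n <- length(v)
    if (n == 0) {
      warning("group '", g, "' is empty after exclusions; omitted")
      return(NULL)
    }
    x <- sum(v == "SOMATIC")
    ci <- wilson_interval(x, n, conf)
    rate <- x / n
    pct <- if (n < 50) round(rate * 100, 1) else round(rate * 100)
    data.frame(group = g, n_somatic = x, n_total = n, rate = rate,
               percent_display = pct,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC for caller quality scores against validation outcome
#'
#' Sweeps all distinct score thresholds (call positive when
#' `score >= threshold`), records the true- and false-positive rates, and
#' computes the area under the curve by the trapezoid rule. Tied scores
#' form a single threshold, so the trapezoidal AUC equals the rank
#' statistic (probability that a random validated call outscores a random
#' non-validated call, ties counted half).
#'
#' @param scores numeric quality scores.
#' @param outcomes logical/0-1: `TRUE` for validated (SOMATIC) calls.
#' @return An object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr` (each starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both validated and non-validated calls", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & outcomes) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !outcomes) / n_neg,
                numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  if (utils::tail(tpr, 1) != 1 || utils::tail(fpr, 1) != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
    thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", length(x$thresholds), "thresholds, AUC =",
      formatC(x$auc, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Two-proportion comparison of validation rates
#'
#' Convenience test for contrasts such as consensus vs single-caller
#' validation rates; uses Fisher's exact test on the 2x2 table.
#'
#' @param x1,n1 successes and totals in group 1.
#' @param x2,n2 successes and totals in group 2.
#' @param alternative passed to [stats::fisher.test()].
#' @return the `htest` object.
#' @export
compare_rates <- function(x1, n1, x2, n2, alternative = "two.sided") {
  stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2),
                     alternative = alternative)
}
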