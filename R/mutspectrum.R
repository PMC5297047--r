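#' Extrapolate the genome-wide true mutation count
#'
#' Scales a raw called-mutation count by an orthogonally measured
#' validation rate; the result is floored to a whole mutation count (e.g.
#' 13811 calls at a 23% validation rate gives floor(3176.53) = 3176).
#'
#' @param n_called number of raw calls.
#' @param validation_rate fraction of calls expected to be true, in [0,1].
#' @return integer expected number of true mutations.
#' @export
extrapolate_true_count <- function(n_called, validation_rate) {
  if (n_called < 0 || validation_rate < 0 || validation_rate > 1) {
    stop("n_called must be >= 0 and validation_rate in [0,1]",
         call. = FALSE)
  }
  as.integer(floor(n_called * validation_rate))
}

#' Mutations per megabase
#'
#' @param expected_true extrapolated true mutation count.
#' @param genome_size_bp genome size in bp (> 0).
#' @return full-precision mutations/Mb; format with
#'   [format_rate_per_mb()] for display.
#' @export
rate_per_mb <- function(expected_true, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0", call. = FALSE)
  if (expected_true < 0) stop("expected_true must be >= 0", call. = FALSE)
  expected_true * 1e6 / genome_size_bp
}

#' Display a per-Mb rate truncated (not rounded) to two decimals
#'
#' Truncation is the display convention that turns 2.2485 into "2.24".
#'
#' @param rate numeric rate.
#' @return character.
#' @export
format_rate_per_mb <- function(rate) {
  sprintf("%.2f", trunc(rate * 100) / 100)
}

#' Genome-wide mutation-rate estimate
#'
#' Bundles the extrapolation: called count x validation rate, floored,
#' divided by the genome size. The default genome size (1,412,464,843 bp)
#' is a configuration parameter, not derived from any FASTA, so toy genomes
#' can coexist with whole-genome arithmetic.
#'
#' @param n_called raw called-mutation count.
#' @param validation_rate orthogonal validation rate in [0,1].
#' @param genome_size_bp genome size in bp.
#' @return object of class `mutation_rate_estimate` with fields n_called,
#'   validation_rate, expected_true, genome_size_bp, rate_per_mb (full
#'   precision) and rate_per_mb_display (truncated string).
#' @examples
#' mutation_rate_estimate(13811, 0.23)
#' @export
mutation_rate_estimate <- function(n_called, validation_rate,
                                   genome_size_bp = 1412464843) {
  expected_true <- extrapolate_true_count(n_called, validation_rate)
  r <- rate_per_mb(expected_true, genome_size_bp)
  structure(list(n_called = n_called, validation_rate = validation_rate,
                 expected_true = expected_true,
                 genome_size_bp = genome_size_bp,
                 rate_per_mb = r,
                 rate_per_mb_display = format_rate_per_mb(r)),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("mutation_rate_estimate:", x$n_called, "calls x",
      x$validation_rate, "validation rate ->", x$expected_true,
      "expected true mutations;", x$rate_per_mb_display, "per Mb over",
      x$genome_size_bp, "bp\n")
  invisible(x)
}

#' The 96 trinucleotide-context labels
#'
#' Ordered by pyrimidine-normalized class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank, then 3' flank, e.g. `"A[C>A]A"`.
#' @return character vector of length 96.
#' @export
sbs_context_levels <- function() {
  out <- character(0)
  for (cls in SBS_CLASSES) {
    for (five in BASES) {
      for (three in BASES) {
        out <- c(out, paste0(five, "[", cls, "]", three))
      }
    }
  }
  out
}

#' Pyrimidine-normalized substitution spectrum with trinucleotide contexts
#'
#' Counts variants over the 6 substitution classes and the 96 trinucleotide
#' contexts. Purine-reference substitutions are reverse-complemented onto
#' the pyrimidine strand (G>A with flanks c..t is counted as C>T in the
#' reverse-complemented context). Each variant's REF base must match the
#' reference sequence; mismatches raise an error listing the offending
#' loci. Variants at the first or last base of a chromosome have no full
#' trinucleotide context: they are counted in the 6 classes but excluded
#' from the 96-context table (tallied in `n_context_excluded`).
#'
#' @param variants data frame with chrom, pos, ref, alt.
#' @param reference `DNAStringSet` or FASTA path.
#' @return object of class `substitution_spectrum`: `class_counts` (named
#'   6-vector), `context_counts` (named 96-vector), `n_total`,
#'   `n_context_excluded`.
#' @export
substitution_spectrum <- function(variants, reference) {
  reference <- as_reference(reference)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  ref_names <- stats::setNames(names(reference),
                               norm_chrom(names(reference)))
  chrom <- ref_names[norm_chrom(variants$chrom)]
  if (anyNA(chrom)) {
    bad <- unique(variants$chrom[is.na(chrom)])
    stop("chromosome(s) not in reference: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(reference), names(reference))

  n <- nrow(variants)
  ref_obs <- toupper(variants$ref); alt_obs <- toupper(variants$alt)
  genome_base <- vapply(seq_len(n), function(i)
    as.character(Biostrings::subseq(reference[[chrom[i]]],
                                    variants$pos[i], variants$pos[i])),
    character(1))
  mism <- genome_base != ref_obs
  if (any(mism)) {
    stop("REF does not match the reference at: ",
         paste(paste0(variants$chrom[mism], ":", variants$pos[mism]),
               collapse = ", "), call. = FALSE)
  }

  is_pyr <- ref_obs %in% c("C", "T")
  cls <- ifelse(is_pyr, paste0(ref_obs, ">", alt_obs),
                paste0(complement_base(ref_obs), ">",
                       complement_base(alt_obs)))
  if (!all(cls %in% SBS_CLASSES)) {
    stop("invalid substitution (ref == alt or non-ACGT)", call. = FALSE)
  }
  class_counts <- stats::setNames(integer(6), SBS_CLASSES)
  tab <- table(factor(cls, levels = SBS_CLASSES))
  class_counts[names(tab)] <- as.integer(tab)

  has_ctx <- variants$pos > 1 & variants$pos < lens[chrom]
  ctx_counts <- stats::setNames(integer(96), sbs_context_levels())
  if (any(has_ctx)) {
    idx <- which(has_ctx)
    trip <- vapply(idx, function(i)
      as.character(Biostrings::subseq(reference[[chrom[i]]],
                                      variants$pos[i] - 1L,
                                      variants$pos[i] + 1L)),
      character(1))
    trip <- ifelse(is_pyr[idx], trip, revcomp(trip))
    lab <- paste0(substr(trip, 1, 1), "[", cls[idx], "]",
                  substr(trip, 3, 3))
    tab <- table(factor(lab, levels = sbs_context_levels()))
    ctx_counts[names(tab)] <- as.integer(tab)
  }

  structure(list(class_counts = class_counts,
                 context_counts = ctx_counts,
                 n_total = n,
                 n_context_excluded = sum(!has_ctx)),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("substitution_spectrum over", x$n_total, "SNVs\n")
  pct <- round(100 * x$class_counts / max(1, x$n_total), 1)
  for (cls in SBS_CLASSES) {
    cat(sprintf("  %s: %6d (%5.1f%%)\n", cls, x$class_counts[[cls]],
                pct[[cls]]))
  }
  if (x$n_context_excluded > 0) {
    cat("  (", x$n_context_excluded,
        "variant(s) at sequence ends excluded from contexts )\n")
  }
  invisible(x)
}

#' TCA/TCG/TCC and dipyrimidine context report for C>T mutations
#'
#' Reports the fraction of mutations at the UV-relevant C>T contexts
#' T\[C>T\]A, T\[C>T\]G and T\[C>T\]C, plus the overall dipyrimidine
#' fraction (C>T mutations whose 5' neighbour is a pyrimidine, after
#' strand normalization). Fractions are given over two denominators —
#' all mutations (`frac_of_all`) and C>T mutations only (`frac_of_ct`) —
#' because published summaries are often ambiguous about which is meant.
#'
#' @param spectrum a [substitution_spectrum()] result.
#' @return data frame with rows TCA, TCG, TCC, dipyrimidine.
#' @export
dipyrimidine_report <- function(spectrum) {
  stopifnot(inherits(spectrum, "substitution_spectrum"))
  cc <- spectrum$context_counts
  n_all <- spectrum$n_total
  n_ct <- spectrum$class_counts[["C>T"]]
  pick <- function(labels) sum(cc[labels])
  ct_ctx <- grep("\\[C>T\\]", names(cc), value = TRUE)
  dipyr <- ct_ctx[substr(ct_ctx, 1, 1) %in% c("C", "T")]
  rows <- list(
    TCA = pick("T[C>T]A"),
    TCG = pick("T[C>T]G"),
    TCC = pick("T[C>T]C"),
    dipyrimidine = pick(dipyr)
  )
  data.frame(context = names(rows),
             count = unlist(rows, use.names = FALSE),
             frac_of_all = if (n_all > 0)
               unlist(rows, use.names = FALSE) / n_all else NA_real_,
             frac_of_ct = if (n_ct > 0)
               unlist(rows, use.names = FALSE) / n_ct else NA_real_,
             stringsAsFactors = FALSE)
}

#' Classify variants into exonic / intronic / intergenic regions
#'
#' Precedence when intervals overlap is exonic > intronic > intergenic.
#' Gene models may be `gene_model` objects ([make_gene_model()]) or BED
#' paths (BED12 blocks are exons; see [read_gene_model_bed()]). BED
#' intervals are 0-based half-open on disk; variants are 1-based.
#'
#' @param variants data frame with chrom, pos.
#' @param gene_model `gene_model` object or BED path.
#' @return object of class `region_breakdown`: per-region counts and
#'   fractions, plus the per-variant labels.
#' @export
region_breakdown <- function(variants, gene_model) {
  if (is.character(gene_model)) gene_model <- read_gene_model_bed(gene_model)
  stopifnot(inherits(gene_model, "gene_model"))
  gr <- GenomicRanges::GRanges(
    norm_chrom(variants$chrom),
    IRanges::IRanges(variants$pos, width = 1L))
  gn <- gene_model$genes
  ex <- gene_model$exons
  gn2 <- GenomicRanges::GRanges(
    norm_chrom(GenomicRanges::seqnames(gn)), IRanges::ranges(gn))
  ex2 <- GenomicRanges::GRanges(
    norm_chrom(GenomicRanges::seqnames(ex)), IRanges::ranges(ex))
  in_gene <- IRanges::overlapsAny(gr, gn2)
  in_exon <- IRanges::overlapsAny(gr, ex2)
  label <- ifelse(in_exon, "exonic",
                  ifelse(in_gene, "intronic", "intergenic"))
  counts <- c(exonic = sum(label == "exonic"),
              intronic = sum(label == "intronic"),
              intergenic = sum(label == "intergenic"))
  structure(list(counts = counts,
                 fractions = counts / max(1, sum(counts)),
                 labels = label),
            class = "region_breakdown")
}

#' @export
print.region_breakdown <- function(x, ...) {
  for (r in names(x$counts)) {
    cat(sprintf("  %-10s %6d (%5.1f%%)\n", r, x$counts[[r]],
                100 * x$fractions[[r]]))
  }
  invisible(x)
}

#' Cosine similarity of a spectrum to reference mutational signatures
#'
#' Normalizes the 96-context counts to a probability vector and ranks
#' reference signatures (96 x K matrix, columns nonnegative and summing to
#' 1) by cosine similarity, ties broken by column order.
#'
#' @param spectrum a [substitution_spectrum()] or a 96-vector of counts.
#' @param signatures numeric matrix 96 x K, rownames matching
#'   [sbs_context_levels()] (reordered if needed), or a TSV path (first
#'   column context labels).
#' @return data frame (signature, cosine) sorted by decreasing similarity.
#' @export
signature_similarity <- function(spectrum, signatures) {
  v <- if (inherits(spectrum, "substitution_spectrum")) {
    spectrum$context_counts
  } else {
    spectrum
  }
  if (length(v) != 96) stop("spectrum must have 96 contexts", call. = FALSE)
  if (sum(v) <= 0) stop("spectrum is empty; similarity undefined",
                        call. = FALSE)
  if (is.character(signatures)) signatures <- read_signature_tsv(signatures)
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96) {
    stop("signature matrix must have 96 rows", call. = FALSE)
  }
  if (!is.null(rownames(signatures)) &&
      all(sbs_context_levels() %in% rownames(signatures))) {
    signatures <- signatures[sbs_context_levels(), , drop = FALSE]
  }
  if (any(signatures < 0)) stop("signatures must be nonnegative",
                                call. = FALSE)
  csums <- colSums(signatures)
  if (any(abs(csums - 1) > 1e-6)) {
    stop("signature columns must sum to 1", call. = FALSE)
  }
  if (is.null(colnames(signatures))) {
    colnames(signatures) <- paste0("signature_", seq_len(ncol(signatures)))
  }
  vn <- as.numeric(v) / sum(v)
  cosine <- vapply(seq_len(ncol(signatures)), function(k) {
    s <- signatures[, k]
    den <- sqrt(sum(vn^2)) * sqrt(sum(s^2))
    if (den == 0) 0 else sum(vn * s) / den
  }, numeric(1))
  ord <- order(-cosine, seq_along(cosine))
  data.frame(signature = colnames(signatures)[ord],
             cosine = cosine[ord], stringsAsFactors = FALSE)
}

#' Generate a toy mutational-signature matrix
#'
#' Dirichlet-like random profiles over the 96 contexts, for testing and
#' demonstrations (no external signature catalogue is bundled).
#'
#' @param k number of signatures.
#' @param seed integer seed.
#' @param concentration gamma shape; small values give spiky signatures.
#' @return 96 x k matrix, columns summing to 1.
#' @export
random_signature_matrix <- function(k = 5L, seed = 1L, concentration = 0.3) {
  with_seed(seed, {
    m <- matrix(stats::rgamma(96 * k, shape = concentration), nrow = 96)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- sbs_context_levels()
    colnames(m) <- paste0("signature_", seq_len(k))
    m
  })
}

#' Read / write a signature matrix TSV (96 rows, first column `context`)
#' @param path TSV path.
#' @return matrix with context rownames.
#' @export
read_signature_tsv <- function(path) {
  df <- read_tsv_checked(path, required = "context")
  m <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- df$context
  m
}

#' @rdname read_signature_tsv
#' @param m signature matrix.
#' @export
write_signature_tsv <- function(m, path) {
  df <- data.frame(context = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}
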