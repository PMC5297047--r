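#' Map fish genes to human ortholog symbols
#'
#' For each fish gene present in the ortholog table, the highest-confidence
#' human symbol is kept (ties broken by lexicographically smallest symbol);
#' fish genes absent from the table are reported as unmapped. The unique
#' human symbol set is de-duplicated, so many fish genes collapsing onto
#' one human gene contribute a single symbol.
#'
#' @param fish_genes character vector of fish gene identifiers.
#' @param orthologs data frame with columns `fish_id`, `human_symbol`,
#'   `score` (DIOPT-style), or a path to such a TSV.
#' @return list of class `ortholog_mapping`: `mapping` (data frame fish_id,
#'   human_symbol, score), `human_symbols` (unique, sorted), `unmapped`,
#'   and a `report` with n_input, n_mapped, n_unique_human.
#' @export
map_orthologs <- function(fish_genes, orthologs) {
  if (is.character(orthologs) && length(orthologs) == 1L) {
    orthologs <- read_tsv_checked(orthologs,
                                  required = c("fish_id", "human_symbol",
                                               "score"))
  }
  need <- c("fish_id", "human_symbol", "score")
  if (!all(need %in% names(orthologs))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fish_genes <- unique(as.character(fish_genes))
  tab <- orthologs[orthologs$fish_id %in% fish_genes, need, drop = FALSE]
  # best score first, then lexicographic human symbol for ties
  tab <- tab[order(tab$fish_id, -tab$score, tab$human_symbol), ,
             drop = FALSE]
  best <- tab[!duplicated(tab$fish_id), , drop = FALSE]
  rownames(best) <- NULL
  unmapped <- setdiff(fish_genes, best$fish_id)
  human <- sort(unique(best$human_symbol))
  structure(list(mapping = best,
                 human_symbols = human,
                 unmapped = unmapped,
                 report = list(n_input = length(fish_genes),
                               n_mapped = nrow(best),
                               n_unique_human = length(human))),
            class = "ortholog_mapping")
}

#' @export
print.ortholog_mapping <- function(x, ...) {
  cat("ortholog_mapping:", x$report$n_input, "input genes ->",
      x$report$n_mapped, "mapped ->", x$report$n_unique_human,
      "unique human symbols (", length(x$unmapped), "unmapped )\n")
  invisible(x)
}

#' Overlap of two gene sets with a hypergeometric enrichment test
#'
#' Computes `A` intersect `B` and a one-sided Fisher exact p-value for the
#' overlap being at least as large as observed, given a stated universe
#' size (hypergeometric upper tail over the 2x2 table in/out of A by
#' in/out of B).
#'
#' @param a,b character vectors of gene symbols.
#' @param universe integer universe size; must be at least `|A union B|`.
#' @return list: `overlap` (character), `n_overlap`, `p_value`, and the
#'   2x2 `table`.
#' @export
gene_set_overlap <- function(a, b, universe) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n_union <- length(union(a, b))
  if (universe < n_union) {
    stop("universe (", universe, ") smaller than |A union B| (", n_union,
         ")", call. = FALSE)
  }
  ov <- intersect(a, b)
  k <- length(ov)
  # P(X >= k) with X ~ Hypergeometric(|A| marked, universe - |A|, draws |B|)
  p <- stats::phyper(k - 1, length(a), universe - length(a), length(b),
                     lower.tail = FALSE)
  tab <- matrix(c(k, length(b) - k,
                  length(a) - k, universe - length(a) - length(b) + k),
                nrow = 2,
                dimnames = list(in_A = c("yes", "no"),
                                in_B = c("yes", "no")))
  list(overlap = sort(ov), n_overlap = k, p_value = p, table = tab)
}

#' Per-gene mutation frequencies in named cohorts
#'
#' Each (cohort, sample, gene) combination counts once regardless of how
#' many distinct mutations that sample carries in the gene. Cohort
#' denominators default to the number of distinct samples observed in the
#' table and can be overridden with `cohort_sizes` (e.g. when the table
#' only lists mutated samples out of a larger sequenced cohort).
#' MAF-style column names (`Hugo_Symbol`, `Tumor_Sample_Barcode`) are
#' accepted.
#'
#' @param mutations data frame (or TSV path) with columns `cohort`,
#'   `sample_id`, `gene`.
#' @param genes genes to report; defaults to all genes in the table.
#' @param cohort_sizes optional named vector of per-cohort sample counts.
#' @return data frame of class `cohort_frequency_table`: gene, cohort,
#'   n_mutated, n_samples, frequency, percent (integer display).
#' @export
cohort_frequencies <- function(mutations, genes = NULL,
                               cohort_sizes = NULL) {
  if (is.character(mutations) && length(mutations) == 1L) {
    mutations <- read_tsv_checked(mutations)
  }
  nm <- names(mutations)
  if ("Hugo_Symbol" %in% nm && !"gene" %in% nm) {
    mutations$gene <- mutations$Hugo_Symbol
  }
  if ("Tumor_Sample_Barcode" %in% nm && !"sample_id" %in% nm) {
    mutations$sample_id <- mutations$Tumor_Sample_Barcode
  }
  need <- c("cohort", "sample_id", "gene")
  if (!all(need %in% names(mutations))) {
    stop("mutation table must have columns ", paste(need, collapse = ", "),
         " (MAF-style Hugo_Symbol/Tumor_Sample_Barcode accepted)",
         call. = FALSE)
  }
  mutations <- unique(mutations[, need, drop = FALSE])
  cohorts <- unique(mutations$cohort)
  if (!is.null(cohort_sizes)) {
    unknown <- setdiff(names(cohort_sizes), cohorts)
    # sizes may legitimately name cohorts with zero mutated samples
    cohorts <- union(cohorts, names(cohort_sizes))
  }
  n_samples <- vapply(cohorts, function(co) {
    if (!is.null(cohort_sizes) && co %in% names(cohort_sizes)) {
      as.integer(cohort_sizes[[co]])
    } else {
      length(unique(mutations$sample_id[mutations$cohort == co]))
    }
  }, integer(1))
  names(n_samples) <- cohorts
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  out <- expand.grid(gene = genes, cohort = cohorts,
                     stringsAsFactors = FALSE)
  out$n_mutated <- mapply(function(g, co) {
    length(unique(mutations$sample_id[mutations$gene == g &
                                        mutations$cohort == co]))
  }, out$gene, out$cohort)
  out$n_samples <- n_samples[out$cohort]
  out$frequency <- out$n_mutated / out$n_samples
  out$percent <- round(out$frequency * 100)
  rownames(out) <- NULL
  class(out) <- c("cohort_frequency_table", "data.frame")
  out
}

#' Compare per-gene mutation frequencies between two cohorts
#'
#' For each gene, builds the 2x2 table of mutated/unmutated samples in the
#' baseline and resistant cohorts and reports the frequency difference in
#' percentage points, the cross-product odds ratio (Haldane 0.5 correction
#' when any cell is zero), a Fisher exact p-value, and Benjamini-Hochberg
#' adjusted q-values across the tested genes. The test columns are a
#' supplementary aid for ranking: raw frequency differences are the primary
#' readout.
#'
#' @param freq_table a [cohort_frequencies()] result.
#' @param baseline,resistant cohort labels present in the table.
#' @param alternative passed to [stats::fisher.test()]; default
#'   `"two.sided"`.
#' @return data frame: gene, baseline/resistant counts and frequencies,
#'   delta_percent, odds_ratio, p_value, q_value; sorted by q then gene.
#' @export
compare_cohorts <- function(freq_table, baseline, resistant,
                            alternative = "two.sided") {
  stopifnot(is.data.frame(freq_table))
  cohorts <- unique(freq_table$cohort)
  for (lab in c(baseline, resistant)) {
    if (!lab %in% cohorts) {
      stop("unknown cohort '", lab, "'; valid labels: ",
           paste(cohorts, collapse = ", "), call. = FALSE)
    }
  }
  base <- freq_table[freq_table$cohort == baseline, , drop = FALSE]
  res <- freq_table[freq_table$cohort == resistant, , drop = FALSE]
  if (any(base$n_samples < 1) || any(res$n_samples < 1)) {
    stop("empty cohort", call. = FALSE)
  }
  genes <- intersect(base$gene, res$gene)
  rows <- lapply(genes, function(g) {
    b <- base[base$gene == g, ][1, ]
    r <- res[res$gene == g, ][1, ]
    m <- matrix(c(r$n_mutated, r$n_samples - r$n_mutated,
                  b$n_mutated, b$n_samples - b$n_mutated), nrow = 2)
    if (any(m == 0)) {
      or <- ((m[1, 1] + 0.5) * (m[2, 2] + 0.5)) /
        ((m[1, 2] + 0.5) * (m[2, 1] + 0.5))
    } else {
      or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    }
    p <- stats::fisher.test(m, alternative = alternative)$p.value
    data.frame(gene = g,
               baseline_mutated = b$n_mutated,
               baseline_n = b$n_samples,
               baseline_frequency = b$frequency,
               resistant_mutated = r$n_mutated,
               resistant_n = r$n_samples,
               resistant_frequency = r$frequency,
               delta_percent = (r$frequency - b$frequency) * 100,
               odds_ratio = or,
               p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
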