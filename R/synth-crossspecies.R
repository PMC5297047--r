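#' Simulate ortholog, cohort-mutation and differential-expression tables
#'
#' Generates the cross-species inputs with known ground truth:
#' \itemize{
#'   \item an ortholog table (`fish_id`, `human_symbol`, `score`,
#'     DIOPT-style) in which a configurable fraction of fish genes maps
#'     1:1, a fraction shares its best human symbol with another fish gene
#'     (many:1), and a fraction is unmapped; a further fraction of mapped
#'     genes carries a second, lower-scoring candidate row so that
#'     best-score selection is exercised;
#'   \item two cohort mutation tables (`cohort`, `sample_id`, `gene`):
#'     per sample, each gene mutates independently at `baseline_rate`,
#'     multiplied in the resistant cohort by `per_gene_enrichment` for the
#'     named genes;
#'   \item a differential-expression gene list (`fish_id`, `log2fc`,
#'     `fdr`).
#' }
#'
#' @param n_genes number of fish genes in the universe.
#' @param cohort_sizes named integer vector, e.g.
#'   `c(baseline = 346, resistant = 78)`; the first name is treated as the
#'   baseline cohort.
#' @param per_gene_enrichment named numeric: fold-increase of the mutation
#'   rate in the resistant cohort for those genes (all other genes 1).
#' @param baseline_rate per-gene per-sample mutation probability in the
#'   baseline cohort.
#' @param seed integer seed.
#' @param ortholog_fractions fractions of fish genes that are 1:1,
#'   many:1 and unmapped (must sum to 1).
#' @param multi_candidate_fraction fraction of mapped fish genes given a
#'   second lower-scoring candidate human symbol.
#' @param n_de number of genes in the simulated DE list.
#' @param duplicate_fraction fraction of mutation rows duplicated, to
#'   exercise the one-count-per-sample collapse rule downstream.
#' @param outdir optional directory; when given, `orthologs.tsv`,
#'   `cohort_<name>.tsv` and `de_genes.tsv` are written there.
#' @return list with `orthologs`, `mutations` (one data frame, both
#'   cohorts), `de_genes`, `genes`, and `truth` (the per-gene resistant
#'   rates).
#' @export
simulate_cross_species_tables <- function(n_genes = 500L,
                                          cohort_sizes = c(baseline = 346L,
                                                           resistant = 78L),
                                          per_gene_enrichment = c(
                                            zgene0001 = 3.5,
                                            zgene0002 = 7,
                                            zgene0003 = 2.75),
                                          baseline_rate = 0.02,
                                          seed = 1L,
                                          ortholog_fractions = c(
                                            one_to_one = 0.7,
                                            many_to_one = 0.2,
                                            unmapped = 0.1),
                                          multi_candidate_fraction = 0.3,
                                          n_de = 100L,
                                          duplicate_fraction = 0.02,
                                          outdir = NULL) {
  stopifnot(n_genes >= 2, length(cohort_sizes) == 2,
            !is.null(names(cohort_sizes)),
            baseline_rate > 0, baseline_rate < 1,
            abs(sum(ortholog_fractions) - 1) < 1e-8)
  genes <- sprintf("zgene%04d", seq_len(n_genes))
  enrich <- stats::setNames(rep(1, n_genes), genes)
  if (length(per_gene_enrichment)) {
    unknown <- setdiff(names(per_gene_enrichment), genes)
    if (length(unknown)) {
      stop("per_gene_enrichment names not in the gene universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    enrich[names(per_gene_enrichment)] <- per_gene_enrichment
  }

  with_seed(seed, {
    ## ortholog table ----------------------------------------------------
    n_cat <- apportion(n_genes, ortholog_fractions)
    cat_lab <- rep(c("one_to_one", "many_to_one", "unmapped"), n_cat)
    cat_lab <- sample(cat_lab) # shuffle category over genes
    human <- sprintf("HGENE%04d", seq_len(n_genes))
    best_human <- character(n_genes)
    best_human[cat_lab == "one_to_one"] <- human[cat_lab == "one_to_one"]
    m1 <- which(cat_lab == "many_to_one")
    if (length(m1) >= 2) {
      # pair consecutive many:1 genes onto a shared human symbol
      shared <- human[m1[((seq_along(m1) - 1) %/% 2) * 2 + 1]]
      best_human[m1] <- shared
    } else if (length(m1) == 1) {
      best_human[m1] <- human[m1]
    }
    mapped <- cat_lab != "unmapped"
    orth <- data.frame(fish_id = genes[mapped],
                       human_symbol = best_human[mapped],
                       score = sample(8:15, sum(mapped), replace = TRUE),
                       stringsAsFactors = FALSE)
    extra <- which(stats::runif(nrow(orth)) < multi_candidate_fraction)
    if (length(extra)) {
      orth2 <- orth[extra, , drop = FALSE]
      orth2$human_symbol <- paste0(orth2$human_symbol, "L")
      orth2$score <- pmax(1L, orth2$score -
                            sample(3:6, length(extra), replace = TRUE))
      orth <- rbind(orth, orth2)
    }
    orth <- orth[order(orth$fish_id, -orth$score), ]
    rownames(orth) <- NULL

    ## cohort mutation tables --------------------------------------------
    resistant_name <- names(cohort_sizes)[2]
    mut <- list()
    for (co in names(cohort_sizes)) {
      n_s <- cohort_sizes[[co]]
      rate <- if (co == resistant_name) pmin(1, baseline_rate * enrich) else
        rep(baseline_rate, n_genes)
      hits <- which(matrix(stats::runif(n_s * n_genes), n_s, n_genes) <
                      matrix(rate, n_s, n_genes, byrow = TRUE),
                    arr.ind = TRUE)
      if (nrow(hits)) {
        mut[[co]] <- data.frame(
          cohort = co,
          sample_id = sprintf("%s_s%05d", co, hits[, 1]),
          gene = genes[hits[, 2]], stringsAsFactors = FALSE)
      }
    }
    mutations <- do.call(rbind, mut)
    rownames(mutations) <- NULL
    if (duplicate_fraction > 0 && nrow(mutations)) {
      dup <- which(stats::runif(nrow(mutations)) < duplicate_fraction)
      if (length(dup)) mutations <- rbind(mutations, mutations[dup, ])
    }

    ## DE gene list -------------------------------------------------------
    de_idx <- sample.int(n_genes, min(n_de, n_genes))
    de <- data.frame(fish_id = genes[de_idx],
                     log2fc = stats::rnorm(length(de_idx), 0, 2),
                     fdr = stats::runif(length(de_idx), 0, 0.05),
                     stringsAsFactors = FALSE)

    out <- list(orthologs = orth, mutations = mutations, de_genes = de,
                genes = genes,
                truth = list(enrichment = enrich,
                             baseline_rate = baseline_rate,
                             cohort_sizes = cohort_sizes))
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(orth, file.path(outdir, "orthologs.tsv"))
      for (co in names(cohort_sizes)) {
        write_tsv(mutations[mutations$cohort == co, ],
                  file.path(outdir, paste0("cohort_", co, ".tsv")))
      }
      write_tsv(de, file.path(outdir, "de_genes.tsv"))
    }
    out
  })
}
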