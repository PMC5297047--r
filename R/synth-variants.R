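#' Pyrimidine-normalized substitution classes
#'
#' The six single-nucleotide substitution classes after strand
#' normalization (purine-reference changes are counted on the opposite
#' strand, e.g. G>A as C>T).
#' @export
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# parse "T[C>T]A" -> list(five, class, three)
parse_context <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])\\[([CT]>[ACGT])\\]([ACGT])$", x))[[1]]
  if (length(m) != 4L) {
    stop("Malformed context label '", x,
         "'; expected e.g. \"T[C>T]A\"", call. = FALSE)
  }
  list(five = m[2], class = m[3], three = m[4])
}

#' Plant germline SNPs and clonal somatic SNVs into a reference genome
#'
#' Produces a ground-truth variant set for simulation. Germline
#' heterozygous SNPs are planted independently per position at
#' `germline_rate` (the high SNP density typical of highly polymorphic
#' genomes such as zebrafish is emulated by raising this rate). Exactly
#' `n_somatic` clonal somatic SNVs are planted with substitution classes
#' drawn from `spectrum_weights` and positions stratified over genomic
#' regions according to `region_model` using a toy gene model.
#'
#' Optionally, `context_weights` pins stated fractions of all somatic
#' mutations to exact trinucleotide contexts (e.g.
#' `c("T[C>T]A" = 0.17, "T[C>T]G" = 0.10, "T[C>T]C" = 0.05)`); these
#' counts are drawn from within the corresponding class budget, so realized
#' class proportions still follow `spectrum_weights`.
#'
#' A fraction `confusable_fraction` of germline loci is flagged as
#' "confusable": loci whose matched-normal evidence is too weak for a
#' caller to recognize them as germline. Confusable status is a property of
#' the locus (it models shared input data, e.g. thin normal coverage), so
#' independent callers tend to miscall the same germline loci — the
#' dominant false-positive mode seen in practice.
#'
#' @param reference `DNAStringSet` or FASTA path.
#' @param germline_rate per-bp probability of a germline heterozygous SNP.
#' @param n_somatic number of somatic SNVs to plant.
#' @param spectrum_weights nonnegative 6-vector over [SBS_CLASSES]
#'   (normalized internally).
#' @param region_model fractions over exonic/intronic/intergenic for
#'   somatic placement.
#' @param seed integer seed.
#' @param gene_model a `gene_model`; built with defaults when `NULL`.
#' @param context_weights optional named fractions of all somatic mutations
#'   pinned to exact trinucleotide contexts.
#' @param clonal_fraction expected tumor allele fraction of somatic SNVs
#'   (0.5 = fully clonal heterozygous, 100% purity).
#' @param confusable_fraction fraction of germline loci that callers can
#'   mistake for somatic.
#' @return An object of class `truth_set`: `somatic` and `germline`
#'   data frames, the gene model, the reference and bookkeeping fields.
#' @export
plant_variants <- function(reference,
                           germline_rate = 0.005,
                           n_somatic = 1000L,
                           spectrum_weights = c(`C>A` = 0.08, `C>G` = 0.04,
                                                `C>T` = 0.55, `T>A` = 0.07,
                                                `T>C` = 0.20, `T>G` = 0.06),
                           region_model = c(exonic = 0.02, intronic = 0.35,
                                            intergenic = 0.63),
                           seed = 1L,
                           gene_model = NULL,
                           context_weights = NULL,
                           clonal_fraction = 0.5,
                           confusable_fraction = 0.5) {
  reference <- as_reference(reference)
  stopifnot(germline_rate >= 0, germline_rate < 1, n_somatic >= 0,
            clonal_fraction > 0, clonal_fraction <= 1,
            confusable_fraction >= 0, confusable_fraction <= 1)
  if (length(spectrum_weights) != 6L || any(spectrum_weights < 0) ||
      sum(spectrum_weights) <= 0) {
    stop("spectrum_weights must be 6 nonnegative values with positive sum",
         call. = FALSE)
  }
  names(spectrum_weights) <- SBS_CLASSES
  region_model <- region_model[c("exonic", "intronic", "intergenic")]
  names(region_model) <- c("exonic", "intronic", "intergenic")
  if (anyNA(region_model) || any(region_model < 0) || sum(region_model) <= 0) {
    stop("region_model must give nonnegative fractions for exonic, ",
         "intronic and intergenic", call. = FALSE)
  }
  if (is.null(gene_model)) gene_model <- make_gene_model(reference)

  chroms <- names(reference)
  seq_chr <- lapply(chroms, function(ch) as.character(reference[[ch]]))
  names(seq_chr) <- chroms
  lens <- Biostrings::width(reference); names(lens) <- chroms
  genome_size <- sum(lens)
  if (n_somatic > genome_size) {
    stop("n_somatic exceeds genome capacity", call. = FALSE)
  }

  with_seed(seed, {
    # region code per chromosome (0 intergenic / 1 intronic / 2 exonic)
    rcode <- lapply(chroms, function(ch)
      region_code_vector(gene_model, ch, lens[[ch]]))
    names(rcode) <- chroms

    ## --- germline SNPs -------------------------------------------------
    germ <- lapply(chroms, function(ch) {
      idx <- which(stats::runif(lens[[ch]]) < germline_rate)
      if (length(idx) == 0L) {
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          confusable = logical()))
      }
      refb <- substring(seq_chr[[ch]], idx, idx)
      alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      data.frame(chrom = ch, pos = idx, ref = refb, alt = alt,
                 confusable = stats::runif(length(idx)) < confusable_fraction,
                 stringsAsFactors = FALSE)
    })
    germline <- do.call(rbind, germ)
    rownames(germline) <- NULL

    used <- lapply(chroms, function(ch) {
      u <- logical(lens[[ch]])
      u[germline$pos[germline$chrom == ch]] <- TRUE
      u
    })
    names(used) <- chroms
    if (n_somatic > genome_size - nrow(germline)) {
      stop("n_somatic exceeds available non-germline positions",
           call. = FALSE)
    }

    ## --- somatic allocation -------------------------------------------
    n_class <- apportion(n_somatic, spectrum_weights)
    names(n_class) <- SBS_CLASSES
    ctx_counts <- integer(0)
    if (!is.null(context_weights)) {
      stopifnot(all(context_weights >= 0), sum(context_weights) <= 1)
      ctx_counts <- vapply(context_weights, function(f)
        as.integer(round(f * n_somatic)), integer(1))
      for (nm in names(ctx_counts)) {
        cls <- parse_context(nm)$class
        n_class[cls] <- n_class[cls] - ctx_counts[[nm]]
        if (n_class[cls] < 0) {
          stop("context_weights for '", nm, "' exceed the ", cls,
               " class budget implied by spectrum_weights", call. = FALSE)
        }
      }
    }

    # candidate center positions (1-based) on one chromosome for an exact
    # trinucleotide context, both strands
    context_candidates <- function(ch, ctx) {
      plus <- paste0(ctx$five, substr(ctx$class, 1, 1), ctx$three)
      minus <- revcomp(plus)
      p1 <- Biostrings::start(Biostrings::matchPattern(
        plus, reference[[ch]])) + 1L
      p2 <- Biostrings::start(Biostrings::matchPattern(
        minus, reference[[ch]])) + 1L
      list(plus = p1, minus = setdiff(p2, p1))
    }

    take_stratified <- function(cands_by_chrom, n_take, what) {
      # cands_by_chrom: list(chrom -> integer positions, unused only)
      all_pos <- do.call(rbind, lapply(chroms, function(ch) {
        p <- cands_by_chrom[[ch]]
        if (length(p) == 0L) return(NULL)
        data.frame(chrom = ch, pos = p,
                   region = rcode[[ch]][p], stringsAsFactors = FALSE)
      }))
      if (is.null(all_pos) || nrow(all_pos) < n_take) {
        stop("Not enough available positions to plant ", n_take, " ", what,
             " variants (", if (is.null(all_pos)) 0 else nrow(all_pos),
             " candidates); enlarge the genome or relax the spectrum",
             call. = FALSE)
      }
      per_region <- apportion(n_take, region_model)
      names(per_region) <- names(region_model)
      picked <- integer(0)
      deficit <- 0L
      for (r in names(per_region)) {
        code <- match(r, REGION_LEVELS) - 1L
        pool <- which(all_pos$region == code)
        pool <- setdiff(pool, picked)
        k <- min(per_region[[r]], length(pool))
        deficit <- deficit + per_region[[r]] - k
        if (k > 0) picked <- c(picked, pool[sample.int(length(pool), k)])
      }
      if (deficit > 0L) { # fall back to any remaining candidate
        pool <- setdiff(seq_len(nrow(all_pos)), picked)
        picked <- c(picked, pool[sample.int(length(pool), deficit)])
      }
      all_pos[picked, , drop = FALSE]
    }

    somatic <- list()
    plant_batch <- function(cls, n_take, ctx = NULL) {
      if (n_take == 0L) return(NULL)
      pyr <- substr(cls, 1, 1); pyr_alt <- substr(cls, 3, 3)
      cands <- lapply(chroms, function(ch) {
        if (is.null(ctx)) {
          s <- seq_chr[[ch]]
          p <- which(strsplit(s, "")[[1]] %in% c(pyr, complement_base(pyr)))
        } else {
          cc <- context_candidates(ch, ctx)
          p <- c(cc$plus, cc$minus)
        }
        p[!used[[ch]][p]]
      })
      names(cands) <- chroms
      sel <- take_stratified(cands, n_take,
                             if (is.null(ctx)) cls else
                               paste0(ctx$five, "[", cls, "]", ctx$three))
      refb <- mapply(function(ch, p) substring(seq_chr[[ch]], p, p),
                     sel$chrom, sel$pos, USE.NAMES = FALSE)
      alt <- ifelse(refb == pyr, pyr_alt, complement_base(pyr_alt))
      for (ch in unique(sel$chrom)) {
        used[[ch]][sel$pos[sel$chrom == ch]] <<- TRUE
      }
      data.frame(chrom = sel$chrom, pos = sel$pos, ref = refb, alt = alt,
                 class = cls, region = REGION_LEVELS[sel$region + 1L],
                 stringsAsFactors = FALSE)
    }

    for (nm in names(ctx_counts)) {
      ctx <- parse_context(nm)
      somatic[[length(somatic) + 1L]] <- plant_batch(ctx$class,
                                                     ctx_counts[[nm]], ctx)
    }
    for (cls in SBS_CLASSES) {
      somatic[[length(somatic) + 1L]] <- plant_batch(cls, n_class[[cls]])
    }
    somatic <- do.call(rbind, somatic)
    if (is.null(somatic)) {
      somatic <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            class = character(), region = character(),
                            stringsAsFactors = FALSE)
    }
    somatic <- somatic[order(somatic$chrom, somatic$pos), , drop = FALSE]
    rownames(somatic) <- NULL

    structure(
      list(somatic = somatic,
           germline = germline,
           gene_model = gene_model,
           reference = reference,
           clonal_fraction = clonal_fraction,
           genome_size = genome_size,
           seed = seed),
      class = "truth_set"
    )
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$somatic), "somatic SNVs,",
      nrow(x$germline), "germline SNPs over",
      x$genome_size, "bp;",
      sum(x$germline$confusable), "confusable germline loci\n")
  invisible(x)
}
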