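#' Specification for a synthetic reference genome
#'
#' Describes the toy reference genome used by the synthetic-data generators:
#' number of chromosomes, chromosome length, GC content and the seed that
#' makes generation reproducible. The toy genome stands in for a real
#' reference (e.g. a fish genome assembly) so that every downstream stage of
#' the pipeline can be exercised with known ground truth.
#'
#' @param n_chroms number of chromosomes (>= 1).
#' @param chrom_length length of every chromosome in bp (>= 1000).
#' @param gc_fraction genome GC content, strictly between 0 and 1.
#' @param seed integer seed for reproducible generation.
#' @return An object of class `genome_spec`.
#' @examples
#' spec <- synthetic_genome_spec(1, 100000, 0.4, seed = 7)
#' @export
synthetic_genome_spec <- function(n_chroms = 1L, chrom_length = 100000L,
                                  gc_fraction = 0.4, seed = 1L) {
  if (!is.numeric(n_chroms) || n_chroms < 1) {
    stop("n_chroms must be >= 1", call. = FALSE)
  }
  if (!is.numeric(chrom_length) || chrom_length < 1000) {
    stop("chrom_length must be >= 1000 bp", call. = FALSE)
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length),
         gc_fraction = gc_fraction,
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases with per-base GC probability equal to
#' `spec$gc_fraction`. Generation is deterministic for a fixed seed; two
#' calls with the same spec produce byte-identical FASTA output.
#'
#' @param spec a [synthetic_genome_spec()] object.
#' @param fasta optional path; when given, the genome is written as wrapped
#'   FASTA (60 bp lines, `samtools faidx`-compatible).
#' @return A [Biostrings::DNAStringSet] named `chr1 ... chrN`.
#' @export
generate_reference <- function(spec, fasta = NULL) {
  if (!inherits(spec, "genome_spec")) {
    stop("spec must be created with synthetic_genome_spec()", call. = FALSE)
  }
  gc <- spec$gc_fraction
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  seqs <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_chroms), function(i) {
      paste(sample(BASES, spec$chrom_length, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
  })
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("chr", seq_len(spec$n_chroms))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(ref, fasta, width = 60L)
  }
  ref
}

#' Build a toy gene model over a reference genome
#'
#' Lays out fixed-width genes separated by fixed intergenic gaps; each gene
#' carries `n_exons` equally sized, equally spaced exons totalling
#' `exon_fraction` of the gene body. The layout is deterministic (no RNG).
#' Emitted as BED12 (0-based half-open, exons as blocks) so that downstream
#' coordinate-convention handling is exercised for real.
#'
#' @param reference a `DNAStringSet` (or FASTA path) giving chromosome sizes.
#' @param gene_width gene body width in bp.
#' @param intergenic_width gap between consecutive genes in bp.
#' @param n_exons exons per gene.
#' @param exon_fraction fraction of the gene body that is exonic.
#' @param bed optional path; when given, the model is written as BED12.
#' @return An object of class `gene_model`: a list with `genes` and `exons`
#'   ([GenomicRanges::GRanges]) and the chromosome lengths used.
#' @export
make_gene_model <- function(reference, gene_width = 2000L,
                            intergenic_width = 3000L, n_exons = 3L,
                            exon_fraction = 0.3, bed = NULL) {
  reference <- as_reference(reference)
  stopifnot(gene_width >= n_exons, exon_fraction > 0, exon_fraction <= 1)
  chrom_lengths <- Biostrings::width(reference)
  names(chrom_lengths) <- names(reference)

  exon_w <- max(1L, as.integer(floor(gene_width * exon_fraction / n_exons)))
  # exon starts spread evenly across the gene body
  offsets <- as.integer(round(seq(0, gene_width - exon_w,
                                  length.out = n_exons)))

  genes <- list(); exons <- list()
  gid <- 0L
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq.int(intergenic_width + 1L, by = gene_width + intergenic_width,
                      length.out = max(0L, (len - intergenic_width) %/%
                                         (gene_width + intergenic_width)))
    starts <- starts[starts + gene_width - 1L <= len]
    if (length(starts) == 0L) next
    ids <- sprintf("g%04d", gid + seq_along(starts))
    gid <- gid + length(starts)
    genes[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, width = gene_width), gene_id = ids)
    ex_start <- rep(starts, each = n_exons) + rep(offsets, length(starts))
    exons[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(ex_start, width = exon_w),
      gene_id = rep(ids, each = n_exons))
  }
  genes <- if (length(genes)) do.call(c, unname(genes)) else
    GenomicRanges::GRanges()
  exons <- if (length(exons)) do.call(c, unname(exons)) else
    GenomicRanges::GRanges()
  model <- structure(list(genes = genes, exons = exons,
                          chrom_lengths = chrom_lengths),
                     class = "gene_model")
  if (!is.null(bed)) write_gene_model_bed(model, bed)
  model
}

#' Write a gene model as BED12
#'
#' One line per gene, exons as blocks, 0-based half-open coordinates.
#'
#' @param model a `gene_model` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed <- function(model, path) {
  g <- model$genes
  lines <- vapply(seq_along(g), function(i) {
    gene <- g[i]
    ex <- model$exons[model$exons$gene_id == gene$gene_id]
    ex <- GenomicRanges::sort(ex)
    paste(GenomicRanges::seqnames(gene),
          GenomicRanges::start(gene) - 1L,
          GenomicRanges::end(gene),
          gene$gene_id, 0L, "+",
          GenomicRanges::start(gene) - 1L,
          GenomicRanges::end(gene), "0",
          length(ex),
          paste0(paste(GenomicRanges::width(ex), collapse = ","), ","),
          paste0(paste(GenomicRanges::start(ex) - GenomicRanges::start(gene),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model from a BED file
#'
#' Accepts BED12 (exons taken from blocks) or plain BED (each interval
#' treated as a single-exon gene). Intervals are 0-based half-open on disk
#' and converted to 1-based inclusive internally. Unsorted input is sorted.
#'
#' @param path BED file path.
#' @return A `gene_model` object.
#' @export
read_gene_model_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   stop("Failed to parse BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  gr <- GenomicRanges::sort(gr)
  if (is.null(gr$name)) gr$name <- sprintf("g%04d", seq_along(gr))
  genes <- GenomicRanges::granges(gr)
  genes$gene_id <- gr$name
  if (!is.null(gr$blocks)) {
    ex <- rtracklayer::blocks(gr)
    exons <- unlist(ex, use.names = FALSE)
    exons$gene_id <- rep(gr$name, lengths(ex))
  } else {
    exons <- genes
  }
  structure(list(genes = genes, exons = exons,
                 chrom_lengths = NULL),
            class = "gene_model")
}

# coerce a FASTA path or DNAStringSet to DNAStringSet with clean names
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (!methods::is(reference, "DNAStringSet")) {
    stop("reference must be a DNAStringSet or a FASTA path", call. = FALSE)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

# per-position region code for one chromosome:
# 0 = intergenic, 1 = intronic, 2 = exonic (exon > intron precedence)
region_code_vector <- function(model, chrom, len) {
  code <- integer(len)
  g <- model$genes[norm_chrom(GenomicRanges::seqnames(model$genes)) ==
                     norm_chrom(chrom)]
  e <- model$exons[norm_chrom(GenomicRanges::seqnames(model$exons)) ==
                     norm_chrom(chrom)]
  for (i in seq_along(g)) {
    s <- max(1L, GenomicRanges::start(g[i]))
    t <- min(len, GenomicRanges::end(g[i]))
    if (s <= t) code[s:t] <- 1L
  }
  for (i in seq_along(e)) {
    s <- max(1L, GenomicRanges::start(e[i]))
    t <- min(len, GenomicRanges::end(e[i]))
    if (s <= t) code[s:t] <- 2L
  }
  code
}

REGION_LEVELS <- c("intergenic", "intronic", "exonic")
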