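#' Load SNV calls from a VCF file
#'
#' Reads a tumor/normal VCF via `VariantAnnotation`, splits multi-allelic
#' records into one call per ALT allele, and retains only simple SNVs (REF
#' and ALT both a single A/C/G/T). Records dropped by the SNV filter
#' (indels, symbolic alleles) are counted and reported with a message.
#' Quality is taken from QUAL; tumor/normal allele depths from the AD
#' FORMAT field when present (samples matched by name TUMOR/NORMAL, else
#' first = tumor, second = normal).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param caller_name caller label stored with each call.
#' @return data frame of class `variant_calls` with columns chrom, pos,
#'   ref, alt, caller, quality, t_ref, t_alt, n_ref, n_alt.
#' @export
load_calls <- function(path, caller_name) {
  if (!file.exists(path)) stop("No such VCF: ", path, call. = FALSE)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) {
      stop("Failed to parse VCF '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(vcf) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      caller = character(), quality = numeric(),
                      t_ref = integer(), t_alt = integer(),
                      n_ref = integer(), n_alt = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("load_calls: dropped ", n_drop,
            " non-SNV record(s) (indel/symbolic) from ", basename(path))
  }
  qual <- VariantAnnotation::qual(vcf)

  t_ref <- t_alt <- n_ref <- n_alt <- rep(NA_integer_, length(ref))
  gen <- VariantAnnotation::geno(vcf)
  if ("AD" %in% names(gen) && ncol(vcf) >= 1) {
    ad <- gen$AD
    samp <- colnames(ad)
    ti <- if ("TUMOR" %in% samp) match("TUMOR", samp) else 1L
    ni <- if ("NORMAL" %in% samp) match("NORMAL", samp) else
      if (ncol(ad) >= 2) 2L else NA_integer_
    get_ad <- function(i, slot) {
      if (is.array(ad) && length(dim(ad)) == 3L) {
        return(as.integer(ad[, i, slot]))
      }
      vapply(seq_len(nrow(ad)), function(r) {
        v <- ad[r, i][[1]]
        if (length(v) >= slot && !is.na(v[slot])) as.integer(v[slot])
        else NA_integer_
      }, integer(1))
    }
    t_ref <- get_ad(ti, 1L); t_alt <- get_ad(ti, 2L)
    if (!is.na(ni)) { n_ref <- get_ad(ni, 1L); n_alt <- get_ad(ni, 2L) }
  }

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    caller = caller_name,
    quality = as.numeric(qual),
    t_ref = t_ref, t_alt = t_alt, n_ref = n_ref, n_alt = n_alt,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Consensus report over two or more callsets
#'
#' Variant identity is positional and allelic only — the key is
#' (chromosome, position, ref, alt), with an optional `chr` prefix stripped
#' before matching; quality and depths are ignored.
#'
#' @param callsets named list (>= 2) of call data frames (see
#'   [load_calls()]).
#' @return An object of class `consensus_report` with per-caller counts,
#'   intersection and union counts, and the intersection keys.
#' @export
consensus <- function(callsets) {
  if (!is.list(callsets) || length(callsets) < 2) {
    stop("consensus() needs at least two callsets", call. = FALSE)
  }
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    names(callsets) <- paste0("caller", seq_along(callsets))
  }
  keysets <- lapply(callsets, function(df)
    unique(with(df, variant_key(chrom, pos, ref, alt))))
  per_caller <- vapply(keysets, length, integer(1))
  inter <- Reduce(intersect, keysets)
  uni <- Reduce(union, keysets)
  structure(list(per_caller_counts = per_caller,
                 intersection_count = length(inter),
                 union_count = length(uni),
                 intersection_keys = inter,
                 keysets = keysets),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus_report:\n")
  for (nm in names(x$per_caller_counts)) {
    cat("  ", nm, ": ", x$per_caller_counts[[nm]], " calls\n", sep = "")
  }
  cat("  intersection:", x$intersection_count,
      "  union:", x$union_count, "\n")
  invisible(x)
}

#' Stratify one caller's calls into quality-score quartiles
#'
#' Cut points are the 25/50/75th percentiles of the caller's own quality
#' scores; a call whose score ties a boundary goes to the lower quartile.
#' When all scores are equal every call lands in quartile 1 and a warning
#' is emitted.
#'
#' @param calls data frame with a `quality` column (>= 4 rows).
#' @return An object of class `quartile_strata`: list `Q1..Q4` of call
#'   data frames, with the cut points in `attr(, "cutpoints")`.
#' @export
quartile_stratify <- function(calls) {
  if (nrow(calls) < 4) {
    stop("quartile stratification needs at least 4 calls", call. = FALSE)
  }
  q <- stats::quantile(calls$quality, c(0.25, 0.5, 0.75), names = FALSE)
  bin <- 1L + (calls$quality > q[1]) + (calls$quality > q[2]) +
    (calls$quality > q[3])
  if (all(bin == 1L) && length(unique(calls$quality)) == 1L) {
    warning("all quality scores identical; every call assigned quartile 1")
  }
  strata <- lapply(1:4, function(b) {
    out <- calls[bin == b, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(strata) <- paste0("Q", 1:4)
  structure(strata, class = "quartile_strata", cutpoints = q)
}

#' Validation-panel design
#'
#' The default reproduces a 384-locus panel: `n_overlap` loci called by
#' both callers plus `n_unique_per_caller` loci unique to each of two
#' callers, with unique draws stratified evenly over each caller's quality
#' quartiles. A `n_per_quartile` value can be recorded; when
#' `mode = "per_quartile"`, the panel instead draws `n_per_quartile` loci
#' from every quartile of every caller's full callset (overlap loci then
#' fall inside the per-caller draws rather than being added on top).
#'
#' @param n_overlap loci drawn from the caller intersection.
#' @param n_unique_per_caller loci drawn from each caller's unique calls.
#' @param n_per_quartile per-quartile draw used in `per_quartile` mode.
#' @param mode `"unique_plus_overlap"` (default) or `"per_quartile"`.
#' @return list of class `panel_design`.
#' @export
panel_design <- function(n_overlap = 128L, n_unique_per_caller = 128L,
                         n_per_quartile = 48L,
                         mode = c("unique_plus_overlap", "per_quartile")) {
  mode <- match.arg(mode)
  stopifnot(n_overlap >= 0, n_unique_per_caller >= 0, n_per_quartile >= 0)
  structure(list(n_overlap = as.integer(n_overlap),
                 n_unique_per_caller = as.integer(n_unique_per_caller),
                 n_per_quartile = as.integer(n_per_quartile),
                 mode = mode),
            class = "panel_design")
}

#' Draw a stratified validation panel
#'
#' Samples without replacement, uniformly within each stratum, and
#' deterministically for a fixed seed. Overlap entries come from the
#' caller intersection; unique entries from each caller's calls minus the
#' intersection, spread as evenly as possible over that caller's quality
#' quartiles.
#'
#' @param report a [consensus()] report over exactly two callsets.
#' @param strata named list (one per caller, same names as in `report`) of
#'   [quartile_stratify()] results.
#' @param design a [panel_design()].
#' @param seed integer seed.
#' @return data frame of class `validation_panel` with columns chrom, pos,
#'   ref, alt, source (`overlap` / `<caller>-unique`), quartile.
#' @export
build_panel <- function(report, strata, design = panel_design(), seed = 1L) {
  stopifnot(inherits(report, "consensus_report"),
            inherits(design, "panel_design"))
  callers <- names(report$per_caller_counts)
  if (length(callers) != 2) {
    stop("build_panel supports exactly two callers", call. = FALSE)
  }
  if (!all(callers %in% names(strata))) {
    stop("strata must be a named list covering callers: ",
         paste(callers, collapse = ", "), call. = FALSE)
  }

  stratum_df <- function(caller) {
    st <- strata[[caller]]
    do.call(rbind, lapply(1:4, function(b) {
      df <- st[[b]]
      if (nrow(df) == 0) return(NULL)
      data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                 alt = df$alt,
                 key = with(df, variant_key(chrom, pos, ref, alt)),
                 quartile = b, stringsAsFactors = FALSE)
    }))
  }

  with_seed(seed, {
    entries <- list()
    if (design$mode == "unique_plus_overlap") {
      ## overlap stratum
      if (design$n_overlap > 0) {
        if (length(report$intersection_keys) < design$n_overlap) {
          stop("stratum 'overlap' has ", length(report$intersection_keys),
               " loci; ", design$n_overlap, " requested", call. = FALSE)
        }
        ov_keys <- sample(report$intersection_keys, design$n_overlap)
        s1 <- stratum_df(callers[1])
        ov <- s1[match(ov_keys, s1$key), , drop = FALSE]
        ov$source <- "overlap"
        entries[["overlap"]] <- ov
      }
      ## unique strata, evenly over quartiles
      per_q <- apportion(design$n_unique_per_caller, rep(1, 4))
      for (caller in callers) {
        if (design$n_unique_per_caller == 0) next
        sdf <- stratum_df(caller)
        sdf <- sdf[!(sdf$key %in% report$intersection_keys), , drop = FALSE]
        sdf <- sdf[!duplicated(sdf$key), , drop = FALSE]
        got <- list()
        for (b in 1:4) {
          pool <- sdf[sdf$quartile == b, , drop = FALSE]
          if (nrow(pool) < per_q[b]) {
            stop("stratum '", caller, " unique, quartile ", b, "' has ",
                 nrow(pool), " loci; ", per_q[b], " requested",
                 call. = FALSE)
          }
          got[[b]] <- pool[sample.int(nrow(pool), per_q[b]), , drop = FALSE]
        }
        u <- do.call(rbind, got)
        u$source <- paste0(caller, "-unique")
        entries[[caller]] <- u
      }
    } else { # per_quartile mode: n_per_quartile from every caller quartile
      for (caller in callers) {
        sdf <- stratum_df(caller)
        got <- list()
        for (b in 1:4) {
          pool <- sdf[sdf$quartile == b, , drop = FALSE]
          if (nrow(pool) < design$n_per_quartile) {
            stop("stratum '", caller, " quartile ", b, "' has ",
                 nrow(pool), " loci; ", design$n_per_quartile,
                 " requested", call. = FALSE)
          }
          got[[b]] <- pool[sample.int(nrow(pool), design$n_per_quartile),
                           , drop = FALSE]
        }
        u <- do.call(rbind, got)
        u$source <- ifelse(u$key %in% report$intersection_keys, "overlap",
                           paste0(caller, "-unique"))
        entries[[caller]] <- u
      }
    }
    panel <- do.call(rbind, entries)
    if (is.null(panel)) {
      panel <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          key = character(), quartile = integer(),
                          source = character(), stringsAsFactors = FALSE)
    }
    panel <- panel[!duplicated(panel$key), , drop = FALSE]
    rownames(panel) <- NULL
    class(panel) <- c("validation_panel", "data.frame")
    attr(panel, "design") <- design
    attr(panel, "seed") <- seed
    panel
  })
}
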