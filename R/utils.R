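#' @keywords internal
"_PACKAGE"

# Run code under a fixed seed without disturbing the caller's RNG stream.
# All stochastic operations in the package route through this, so no
# function mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Chromosome dialect normalization: "chr1" and "1" refer to the same
# sequence when callsets from different tools are matched.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[b])), collapse = "")
  }, character(1))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# largest-remainder apportionment: integer counts summing to n,
# proportional to w (nonnegative weights)
apportion <- function(n, w) {
  stopifnot(all(w >= 0), sum(w) > 0)
  p <- w / sum(w)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

read_tsv_checked <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("File '", path, "' is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
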