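# Independent oracles, deliberately naive implementations.

# pairwise rank AUC: P(score_pos > score_neg) + 0.5 * P(tie)
brute_auc <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# hypergeometric upper tail by explicit PMF summation
brute_hyper_tail <- function(k, size_a, size_b, universe) {
  kk <- k:min(size_a, size_b)
  sum(stats::dhyper(kk, size_a, universe - size_a, size_b))
}

# prefixed gene names, safe for n = 0 (paste0 would yield the bare prefix)
gene_names <- function(prefix, n) {
  if (n > 0) paste0(prefix, seq_len(n)) else character(0)
}

# minimal tumor/normal readcount row builder with exact allele fractions
obs_row <- function(taf, naf, depth = 1000L) {
  t_alt <- as.integer(round(taf * depth))
  n_alt <- as.integer(round(naf * depth))
  data.frame(t_ref = depth - t_alt, t_alt = t_alt,
             n_ref = depth - n_alt, n_alt = n_alt)
}

# reference rule, written straight from the published cutoffs
oracle_verdict <- function(taf, naf, tmin = 0.05, nmax = 0.02) {
  if (taf < tmin) return("FAIL")
  if (naf < nmax) return("SOMATIC")
  "GERMLINE"
}
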