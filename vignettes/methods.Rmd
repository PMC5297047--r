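---
title: "Methods: consensus calling, orthogonal validation and mutation spectra in xspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling, orthogonal validation and mutation spectra in xspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspec)
```

# The analysis model

`xspec` implements the downstream half of a tumor/normal whole-genome
point-mutation study in a highly polymorphic model organism: two
independent somatic callers are run upstream (out of scope here), and this
package takes over at their VCFs. The statistical backbone is small and
explicit:

* **Consensus.** Variant identity is the tuple (chromosome, position,
  REF, ALT) — 1-based, SNVs only, an optional `chr` prefix stripped.
  For two callers the report satisfies
  $|A \cup B| = |A| + |B| - |A \cap B|$.

* **Validation classification.** At a deep-sequenced locus with tumor
  allele fraction $t$ and normal allele fraction $n$ (each computed as
  alt/(ref+alt)):
  $$\mathrm{verdict} = \begin{cases}
    \mathrm{FAIL} & t < t_{\min} \\
    \mathrm{SOMATIC} & t \ge t_{\min},\; n < n_{\max} \\
    \mathrm{GERMLINE} & t \ge t_{\min},\; n \ge n_{\max}
  \end{cases}$$
  with defaults $t_{\min} = 0.05$, $n_{\max} = 0.02$. The boundary
  semantics (both inequalities closed on the "$\ge$" side) are taken
  verbatim from the published cutoffs; a locus with tumor AF exactly 5%
  and normal AF exactly 2% is GERMLINE. A zero-depth sample makes the AF
  undefined; such loci are flagged indeterminate and excluded from rates,
  except that a FAIL is still issued when the tumor AF alone decides it.

* **Validation rate.** Per group, $\hat p = x/n$ over SOMATIC verdicts
  with a Wilson score interval. Validation studies of this kind usually
  report the bare proportion; we attach an interval because downstream
  decisions (consensus vs single caller) are comparisons of proportions. Display percentages round to the
  nearest integer, except for panels under 50 loci where one decimal is
  kept — the two conventions that reproduce the printed 38 (49/128),
  23 (60/256) and 11.1 (3/27).

* **ROC/AUC.** Thresholds sweep the distinct scores; AUC is the
  trapezoid area, which (ties forming single thresholds) equals the
  Mann–Whitney rank statistic. The test suite checks this equivalence
  against a brute-force pairwise oracle and the invariance of AUC under
  strictly monotone score transforms.

* **Burden extrapolation.** `expected_true = floor(n_called × rate)` and
  `rate_per_mb = expected_true × 10^6 / genome_size`, displayed
  *truncated* to two decimals. Floor and truncation are the only
  conventions that reproduce the printed pair 3176 (from 3176.53) and
  2.24 (from 2.2485…); full precision is always retained in returned
  objects and JSON. The genome size is a configuration parameter
  (default 1,412,464,843 bp, the published denominator), deliberately not
  derived from the FASTA so toy genomes coexist with whole-genome
  arithmetic.

* **Spectrum.** Substitutions are strand-normalized to the pyrimidine
  reference (G>A counted as C>T with reverse-complemented flanks), giving
  6 classes and 96 trinucleotide contexts in COSMIC order. The
  normalization is involutive: complementing the reference and flipping
  all variants leaves the spectrum unchanged (tested exactly). Variants
  at the first/last base of a sequence have no full context; they count
  in the 6 classes and are tallied as context-excluded. The dipyrimidine
  report gives TCA/TCG/TCC and overall dipyrimidine fractions of C>T
  mutations over *two* denominators (all mutations, and C>T only),
  because published summaries are often ambiguous about which is meant;
  the dipyrimidine flag is "pyrimidine immediately 5' of the mutated
  pyrimidine after strand normalization", the standard UV convention.

* **Region annotation.** Precedence exonic > intronic > intergenic.
  Gene models travel as BED (0-based, half-open); variants are 1-based
  inclusive, matching VCF. We emit gene models as BED12 with exons as
  blocks — a plain BED6 file cannot represent an intron/exon structure
  without inventing a name-encoding convention, and BED12 is the
  field-standard BED form of a gene model. Plain BED input is still
  accepted (each interval a single-exon gene).

* **Cross-species comparison.** Ortholog mapping keeps the
  highest-confidence human symbol per fish gene, ties broken
  lexicographically (the upstream tool's multi-hit collapse rule is not
  published; this one is deterministic and auditable). Gene-set overlap
  uses the one-sided hypergeometric tail, cross-checked in tests against
  explicit PMF summation. Cohort frequencies count each (cohort, sample,
  gene) once; denominators default to observed samples and can be
  overridden with external cohort sizes, since mutation tables often list
  only mutated samples, and since "percent of patients" versus "percent
  of samples" is genuinely ambiguous in typical cohort summaries — both
  modes are supported, neither asserted. The per-gene contrast reports
  the frequency delta, the cross-product odds ratio (Haldane 0.5
  correction on zero cells), a Fisher exact p and BH q-values; the tests
  are a supplementary ranking aid for frequency comparisons that are
  usually reported without one.

# The synthetic world

The generator exists because the original sequencing data cannot be
re-analyzed at desk scale. It emulates, with known ground truth:

* a uniform-composition reference genome at a configurable GC fraction
  (default 0.4), deterministic per seed down to the FASTA bytes;
* a deterministic toy gene model: 2 kb genes every 5 kb, three exons
  totalling 30% of the gene body (so ~40% of the genome is genic and
  ~12% exonic);
* germline heterozygous SNPs at `germline_rate` per bp — default 0.005,
  raised to 0.01 in the end-to-end acceptance world to mimic a
  high-polymorphism (zebrafish-like) genome;
* exactly `n_somatic` clonal somatic SNVs with classes apportioned to
  `spectrum_weights` (largest-remainder, so realized class counts are
  exact) and positions stratified over regions by `region_model`
  (defaults 2% exonic / 35% intronic / 63% intergenic, the published
  whole-genome pattern). `context_weights` can pin exact fractions of
  mutations to specific trinucleotide contexts (e.g. 17/10/5% at
  TCA/TCG/TCC) from within the class budget;
* tumor allele fraction of somatic loci defaults to 0.5 — a fully
  clonal, heterozygous, 100%-pure tumor — appropriate for a clonally
  derived cell line, but an assumption we state rather than a measured
  fact, and configurable (`clonal_fraction`);
* deep validation readcounts: Poisson depths around the target, binomial
  alt counts at the clonal fraction (somatic, tumor), 0.5 (germline,
  both samples) or the sequencing error rate (everything else);
* ortholog tables with configurable 1:1 / many:1 / unmapped fractions
  plus lower-scoring second candidates, and two mutation cohorts with
  per-gene enrichment factors applied to the resistant cohort.

## How callers are simulated, and why false positives are shared

Each simulated caller emits a true somatic locus with probability
`sensitivity` and carries a quality score. With `score_informative = TRUE`
true-call scores are drawn 1.5 standard deviations above false-call scores
(normal, unit sd) — enough to reproduce "high scores predict validation"
qualitatively without modeling caller internals; with `FALSE` the two
groups share one distribution and the ROC curve hugs the diagonal.

False positives have two sources with deliberately different structure:

1. **Confusable germline loci.** `plant_variants` marks a fraction
   (default 0.5) of germline SNPs as *confusable* — loci whose
   matched-normal evidence is too thin for any caller to recognize the
   variant as inherited. Each caller then miscalls each confusable locus
   independently with `germline_call_prob`. Because confusability is a
   property of the locus (it models the shared input data, i.e. normal
   coverage), two independent callers miscall largely the *same* germline
   SNPs.
2. **Random error loci** at `false_positive_rate_per_mb`, independent
   between callers.

This locus-level sharing is a design decision worth being explicit about.
An alternative — each caller drawing false positives independently from
the whole germline pool — makes caller intersection annihilate false
calls, so consensus validation rates would approach 100% regardless of the
per-caller false fraction. That is neither what is observed in practice
(the dominant reported failure mode of validation panels is germline SNPs
missed in a modestly covered normal, and those failures afflict every
caller looking at the same normal) nor consistent with a consensus
validation rate that sits near, not far above, one minus the per-caller
false fraction. With sharing, the consensus keeps
$\approx p^2 C$ of the $C$ confusable loci versus $s^2 N$ of the $N$
somatic loci, so the consensus rate exceeds the per-caller rate whenever
`germline_call_prob` < `sensitivity`, while remaining in its vicinity —
the published pattern.

## The acceptance world

The end-to-end acceptance configuration is: 1 chromosome × 100 kb at GC
0.4; 2,000 somatic SNVs; germline rate 0.01/bp with half confusable; two
callers (informative and uninformative scores) at sensitivity 0.9,
`germline_call_prob` 0.85 and 250 error calls/Mb. In expectation each
caller emits 1800 true + 425 germline + 25 error calls — 20% false calls,
the stated condition. A (128, 128, 48) panel is drawn, validated at depth
500 with error rate 0.002, and classified. Sensitivity began at 0.95 in a
first sketch and was lowered to 0.9 on a structural ground before any
acceptance threshold was evaluated: an informative caller's unique calls
concentrate in the low-score quartiles, and at 0.95 the top-quartile
unique stratum of a 100 kb world cannot supply 32 loci at all.

# Validation-panel design

Two published descriptions of the 384-locus panel disagree: the results
narrative (128 overlap + 128 unique to each of two callers) and the
methods arithmetic (48 per quartile × 4 quartiles × 2 callers, overlap
falling inside the per-caller draws). `panel_design()` defaults to the
first (`mode = "unique_plus_overlap"`, unique draws spread evenly over
quartiles — 32 per quartile for 128) because it matches the figure
labels; the second is available as `mode = "per_quartile"`. The design
triple records `n_per_quartile` either way. Quartile cut points are the
25/50/75th percentiles of the caller's own scores (R type-7 quantiles);
boundary ties go to the lower quartile, and a degenerate all-equal score
vector lands everything in quartile 1 with a warning.

# Numerical and interface conventions

* Coordinates are 1-based inclusive internally (VCF convention); BED is
  converted exactly at the boundary (a 0-based interval [99, 100) is the
  1-based position 100 — tested explicitly).
* All randomness flows through per-operation seeds; no function touches
  the caller's global RNG state (the previous `.Random.seed` is
  restored on exit).
* Integer apportionment (class counts, panel strata) uses the
  largest-remainder method so totals are exact.
* `quantile()` defaults (type 7) define quartile boundaries; ties at a
  boundary go down.
* The per-Mb display truncates; everything else rounds half-even via R's
  `round`. Exact half-percent display cases (e.g. 37.5) therefore follow
  banker's rounding and are not asserted anywhere.
* VCF I/O is delegated to `VariantAnnotation` (multi-allelic records
  split via `expand()`, symbolic alleles and indels dropped with a
  count); parse failures are reported per file, not per line — a known
  departure from the ideal of naming the offending line, accepted as the
  cost of not hand-rolling a VCF parser.
* The simulator config is plain function arguments / CLI flags rather
  than a YAML file: the target environment guarantees no YAML parser,
  and a config format with a single consumer earns nothing.

# What a green test establishes — and what it does not

The synthetic world is i.i.d.-uniform in sequence composition, has no
repeats, mappability structure, coverage waves, strand bias, or indels;
germline SNPs are planted independently per bp rather than in LD blocks;
somatic mutations are fully clonal; validation depths are Poisson-clean.
Green tests therefore establish that the *logic* — set algebra,
classification rules, rate arithmetic, spectrum normalization, coordinate
conventions, test statistics — is correct and that the pipeline recovers
planted truth under its own stated noise model. They do not establish
calling performance on real genomes, nor that the simulated score
distributions resemble any specific caller's.

Known limitations, intentionally out of scope: indel/SV matching,
left-alignment of complex alleles, probabilistic genotype-likelihood
validation models, signature refitting (NMF), per-patient collapsing
beyond a supplied sample→patient mapping, and any re-processing of
external cohort data.
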