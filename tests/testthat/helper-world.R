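# A small shared synthetic world for module tests (kept deliberately small;
# the acceptance suite runs the full-size configuration).
small_world <- function(seed = 101, n_somatic = 400L, chrom_length = 60000L) {
  spec <- synthetic_genome_spec(1, chrom_length, 0.4, seed = seed)
  ref <- generate_reference(spec)
  truth <- plant_variants(ref, germline_rate = 0.005,
                          n_somatic = n_somatic, seed = seed + 1)
  list(spec = spec, ref = ref, truth = truth)
}

dual_callers <- function(truth, seed = 201, sensitivity = 0.95,
                         fp_per_mb = 250, germline_call_prob = 0.9) {
  mA <- caller_model("mutectish", sensitivity, fp_per_mb,
                     score_informative = TRUE, seed = seed,
                     germline_call_prob = germline_call_prob)
  mB <- caller_model("shimmerish", sensitivity, fp_per_mb,
                     score_informative = FALSE, seed = seed + 1,
                     germline_call_prob = germline_call_prob)
  list(mutectish = simulate_caller(truth, mA),
       shimmerish = simulate_caller(truth, mB))
}
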