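# Independent oracles and small fixture builders used across test files.

# brute-force AUROC: count pairwise wins, ties worth one half
auroc_brute = function(pos, neg) {
  s = 0
  for (p in pos) for (q in neg) s = s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# dense validation design: 0.1-h spacing over one 24-h period,
# 100 samples per time point (240 distinct times, n = 24,000)
dense_design = function() {
  design_spec(mode = "interval", first = 0, last = 23.9, interval = 0.1,
              n_per_timepoint = 100L)
}

# abundances of one feature pulled out of a rhythm_sim, in sample order
feature_values = function(sim, feature = "feature_1", cond = 1L) {
  ab = sim$abundance
  ab = ab[ab$feature == feature & ab$cond == cond, ]
  list(time = ab$time, value = ab$abund, mu = ab$mu)
}
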