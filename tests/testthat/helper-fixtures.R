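# Shared fixtures. All synthetic; built in code at test time.

# Default study conditions, fixed seed.
fix_cfg <- function(seed = 1, ...) sim_config(seed = seed, ...)

# Noise-free variant (exact-arithmetic checks).
fix_cfg0 <- function(seed = 1) {
  sim_config(area_noise_cv = 0, rt_jitter_sd = 0, baseline_noise_sd = 0,
             seed = seed)
}

# Analyte panel with zero intercepts (algebraic-identity checks).
fix_cfg_zero_intercept <- function(seed = 1) {
  a <- default_analytes()
  a$intercept <- 0
  sim_config(analytes = a, area_noise_cv = 0, rt_jitter_sd = 0,
             baseline_noise_sd = 0, seed = seed)
}

# Exact series on an analyte's response line.
line_points <- function(slope, intercept, conc) {
  data.frame(concentration = conc, area = slope * conc + intercept)
}

# Mean silhouette width of a 2-D embedding against known labels,
# computed directly from its definition (independent of any clustering
# library).
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
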