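# Shared fixtures and independent oracles.

# Brute-force Hazen quantile: sort, plotting positions (i - 0.5)/n, linear
# interpolation, constant beyond the extreme positions.  Written from the
# definition, independently of stats::quantile.
hazen_oracle <- function(x, level) {
  s <- sort(x)
  n <- length(s)
  p <- level / 100
  pos <- (seq_len(n) - 0.5) / n
  if (p <= pos[1]) return(s[1])
  if (p >= pos[n]) return(s[n])
  i <- max(which(pos <= p))
  s[i] + (s[i + 1] - s[i]) * (p - pos[i]) / (pos[i + 1] - pos[i])
}

# Small cohort configuration (50 included subjects, same age-bin proportions
# as the default design) for fast structural tests.
tiny_config <- function(seed = 1, ...) {
  default_cohort_config(seed = seed,
                        age_bins = default_age_bins(c(8L, 7L, 8L, 7L, 9L, 8L, 3L)),
                        ...)
}

# Noise-free configuration: deterministic thresholds equal to the truth.
noiseless_config <- function(seed = 1) {
  cfg <- tiny_config(seed = seed)
  for (pid in names(cfg$truth)) {
    cfg$truth[[pid]]$sigma_map[] <- 0
    cfg$truth[[pid]]$gh_sd <- 0
    cfg$truth[[pid]]$foveal_sd <- 0
  }
  cfg
}

# A vf_test record built directly from a value vector.
make_test <- function(values, pattern_id = "24-2", eye = "OD",
                      foveal_db = 34, rates = c(0, 0, 0)) {
  structure(list(
    subject_id = "T001", eye = eye, pattern_id = pattern_id,
    values = values, foveal_db = foveal_db,
    fl_rate = rates[1], fp_rate = rates[2], fn_rate = rates[3],
    duration_min = 3.2, attempt = 1L, is_practice = FALSE,
    frame = "as-tested"
  ), class = "vf_test")
}
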