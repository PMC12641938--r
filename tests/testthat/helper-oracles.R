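# Shared fixtures and independent oracles used across test files.

# Constant-position gaze segment sampled at `rate` Hz.
const_stream <- function(duration, x = 0, y = 0, conf = 1, rate = 200,
                         t0 = 0) {
  t <- t0 + seq(0, duration, by = 1 / rate)
  gaze_stream(t, rep(x, length(t)), rep(y, length(t)),
              rep(conf, length(t)), nominal_rate = rate)
}

# Brute-force O(n^2) maximum pairwise separation (independent of the
# compiled path).
brute_dispersion <- function(x, y) {
  if (length(x) < 2) return(0)
  max(dist(cbind(x, y)))
}

# Raw samples with exactly the requested first two moments (n >= 2).
moment_matched <- function(n, mean, sd) {
  base <- seq_len(n)
  z <- (base - mean(base)) / stats::sd(base)
  mean + sd * z
}

# Row-bind fixation-like records for detector-independent tests.
fake_fixations <- function(start, end, cx, cy) {
  data.frame(start = start, end = end, centroid_x = cx, centroid_y = cy,
             dispersion = rep(0, length(start)), duration = end - start,
             n_samples = round((end - start) * 200) + 1L)
}

truth_fixations <- function(session) {
  session$truth[session$truth$kind == "fixation", , drop = FALSE]
}
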