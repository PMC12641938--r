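# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  abort_if(!lo_ok || !hi_ok,
           sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                   name, x,
                   if (closed_lower) "[" else "(", lower, upper,
                   if (closed_upper) "]" else ")"))
  invisible(x)
}

# Inverse-CDF draws from Normal(mean, sd) truncated to [lo, hi].
# sd = 0 degenerates to the (clamped) mean.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# P(lo < Z < hi) computed from whichever tail keeps precision.
pnorm_diff <- function(lo, hi) {
  if (lo > 0) {
    pnorm(lo, lower.tail = FALSE) - pnorm(hi, lower.tail = FALSE)
  } else {
    pnorm(hi) - pnorm(lo)
  }
}

# Mean of a log-normal(mu, sigma) truncated to [a, b].
trunc_lnorm_mean <- function(mu, sigma, a, b) {
  za <- (log(a) - mu) / sigma
  zb <- (log(b) - mu) / sigma
  denom <- pnorm_diff(za, zb)
  if (denom < 1e-300) {
    # numerically degenerate: all mass collapses onto one bound
    return(if (mu > log(b)) b else a)
  }
  exp(mu + sigma^2 / 2) * pnorm_diff(za - sigma, zb - sigma) / denom
}

# Solve for mu so the [a, b]-truncated log-normal has the target mean.
solve_trunc_lnorm_mu <- function(target, sigma, a, b) {
  abort_if(target <= a || target >= b,
           "target mean must lie strictly inside the truncation bounds")
  f <- function(mu) trunc_lnorm_mean(mu, sigma, a, b) - target
  uniroot(f, lower = log(a) - 12 * sigma, upper = log(b) + 12 * sigma,
          tol = 1e-12)$root
}

rtrunc_lnorm <- function(n, mu, sigma, a, b) {
  pa <- plnorm(a, mu, sigma)
  pb <- plnorm(b, mu, sigma)
  # clamp against quantile round-off at extreme parameters
  pmin(pmax(qlnorm(runif(n, pa, pb), mu, sigma), a), b)
}

# Small stable string hash (polynomial rolling, mod large prime) used for
# per-group seed derivation; platform-independent by construction.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 1000003
  as.integer(h)
}

derive_seed <- function(base_seed, label, replicate) {
  as.integer((as.numeric(base_seed) * 7919 + stable_hash(label) * 131 +
                replicate * 17) %% 2147483647)
}
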