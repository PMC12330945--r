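# Independent oracles and small fixture builders shared across tests.

# Bisection root-finder for f(T) = 0.5 on the unfolding curve; independent
# of the closed-form melting_point().
bisect_tm <- function(a, b, p, lo = b - 200, hi = b + 200, tol = 1e-12) {
  g <- function(tt) eval_unfolding(tt, a, b, p) - 0.5
  if (g(lo) < 0 || g(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Reference-normalized model curve f(T)/f(T_ref), built from the exported
# eval_unfolding() only.
rel_model <- function(temperatures, a, b, p, t_ref = min(temperatures)) {
  eval_unfolding(temperatures, a, b, p) / eval_unfolding(t_ref, a, b, p)
}

# Noise-free normalized melting curve for one protein/condition.
make_rel_curve <- function(a, b, p, temperatures = seq(43, 60, length.out = 6)) {
  data.frame(temperature_c = temperatures,
             rel_abundance = rel_model(temperatures, a, b, p))
}
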