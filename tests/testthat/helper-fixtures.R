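# Shared fixture builders; everything is generated in code at test time.

# Batch of fGn estimates under a fixed seed scheme.
fgn_estimates <- function(est_fun, H, n, reps, seed0 = 100L, dt = 2.13, ...) {
  vapply(seq_len(reps), function(i) {
    s <- simulate_fgn(fgn_spec(H, n_samples = n, dt = dt), seed = seed0 + i)
    est_fun(s, ...)
  }, numeric(1))
}

# Small demographic table at the study group sizes (or scaled down).
demo_table <- function(sizes = c(control = 17, covid_h_minus = 32,
                                 covid_h_plus = 14, covid_h_r = 11),
                       seed = 1L) {
  set.seed(seed)
  data.frame(group = rep(names(sizes), sizes),
             age = stats::rnorm(sum(sizes), 42, 12),
             sex = stats::rbinom(sum(sizes), 1, 0.6))
}

# Tiny two-region volume for map-level tests.
two_region_volume <- function(h_lo = 0.4, h_hi = 0.8, d = c(8, 8, 4),
                              n_vol = 250, seed = 7L) {
  mask <- array(TRUE, d)
  h <- array(h_lo, d)
  h[(d[1] / 2 + 1):d[1], , ] <- h_hi
  list(vol = simulate_volume(h, mask, n_vol, 2.13, seed = seed),
       h = h, lo = h == h_lo, hi = h == h_hi)
}
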