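# Shared fixtures, built in code.

# minimal symmetric tree: MPA + two principal branches that are the outlets;
# with radius_ratio = sqrt(0.5) the summed outlet area equals the MPA area,
# so kinetic energy fluxes cancel for steady flow
toy_tree <- function(r_mpa = 1, radius_ratio = sqrt(0.5), L = 5,
                     r_lpa_scale = 1) {
  rp <- r_mpa * radius_ratio
  pa_tree(data.frame(
    id = 1:3, parent = c(NA, 1L, 1L),
    label = c("MPA", "RPA", "LPA"), side = c("MPA", "RPA", "LPA"),
    radius = c(r_mpa, rp, rp * r_lpa_scale), length = c(L, L, L),
    stringsAsFactors = FALSE))
}

constant_waveform <- function(q = 20, period = 1, n = 128) {
  t <- (seq_len(n) - 1) * period / n
  flow_waveform(t, rep(q, n), period)
}

sinusoid_waveform <- function(q0 = 20, q1 = 8, period = 1, n = 256) {
  t <- (seq_len(n) - 1) * period / n
  flow_waveform(t, q0 + q1 * cos(2 * pi * t / period), period)
}

symmetric_rcr_pair <- function(Rp = 10, C = 0.01, Rd = 90, Pd = 0) {
  list(`2` = windkessel_rcr(Rp, C, Rd, Pd),
       `3` = windkessel_rcr(Rp, C, Rd, Pd))
}

# independent complex-series Bessel J0 (converges for moderate |z|)
bessel_j0_complex <- function(z, terms = 60) {
  s <- 0 + 0i
  term <- 1 + 0i
  for (m in seq_len(terms)) {
    s <- s + term
    term <- term * (-(z / 2)^2) / m^2
  }
  s
}

# brute-force signed-rank two-sided p over all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
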