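# Independent numerical oracle: integrate the digestion rate equations
# dB/dd = -k1 B, dN/dd = k1 B - k2 N with a stiff solver, from B(0) = O,
# N(0) = 0. Used to cross-check the closed-form kinetics.
ode_oracle <- function(d, O, k1, k2, rtol = 1e-10) {
  sol <- deSolve::ode(
    c(B = O, N = 0), d,
    function(t, y, parms) list(c(-k1 * y[1], k1 * y[1] - k2 * y[2])),
    NULL, rtol = rtol, atol = 1e-14)
  list(B = sol[, "B"], N = sol[, "N"])
}

# Random kinetic parameter sets: log-uniform rates, uniform occupancy.
random_params <- function(n, k_lo = 0.01, k_hi = 100) {
  data.frame(O = runif(n, 0.05, 1),
             k1 = exp(runif(n, log(k_lo), log(k_hi))),
             k2 = exp(runif(n, log(k_lo), log(k_hi))))
}

# Small deterministic fragment table builder for I/O tests.
frag_df <- function(chrom, start, end) {
  qmnase:::fragment_frame(chrom, as.integer(start), as.integer(end))
}

default_times <- c(1, 2, 5, 15, 40, 60)
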