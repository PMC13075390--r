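# Independent numeric oracles used across the suite. These never call the
# code paths they check.

# Discretized parallel-tube steady state: N well-stirred segments in series,
# unbound intrinsic clearance spread evenly along the tube. Returns the
# hepatic availability and the tube-average unbound concentration relative
# to the inlet (trapezoid average of the segment boundary concentrations).
tube_oracle <- function(fu_clint_over_q, n = 1e4) {
  x <- fu_clint_over_q / n
  c_bound <- cumprod(c(1, rep(1 / (1 + x), n)))
  fh <- c_bound[n + 1]
  avg <- sum((c_bound[-1] + c_bound[-(n + 1)]) / 2) / n
  list(F_H = fh, kpuu = avg)
}

# Well-stirred steady state solved numerically: Q*(Cin - Cout) = fuCLint*Cout
# (unbound basis, f_u folded into the clearance term). Root-found, not
# rearranged, so it is independent of the closed forms under test.
wsm_oracle <- function(fu_clint, q, c_in = 1) {
  f <- function(c_out) q * (c_in - c_out) - fu_clint * c_out
  c_out <- stats::uniroot(f, c(0, c_in), tol = 1e-14)$root
  list(F_H = c_out / c_in, kpuu = c_out / c_in)
}

# Flow-unlimited extended-clearance steady state under constant-rate input:
# solve the 2x2 linear system for blood and hepatocyte unbound
# concentrations (input R into blood; elimination only inside the
# hepatocyte) and report the unbound liver-to-blood ratio.
ecm_oracle <- function(influx, efflux, cl_int, rate_in = 1) {
  a <- matrix(c(-influx, efflux,
                influx, -(efflux + cl_int)), 2, 2, byrow = TRUE)
  conc <- solve(a, c(-rate_in, 0))
  conc[2] / conc[1]
}

# Brute-force trapezoid AUC/AUMC of an exp_sum on a dense grid (oracle for
# the closed-form moments at modest accuracy).
numeric_moments <- function(e, tmax, dt = 0.01) {
  t <- seq(0, tmax, by = dt)
  y <- eval_exp_sum(e, t)
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  aumc <- sum((t[-1] * y[-1] + t[-length(y)] * y[-length(y)]) / 2 * diff(t))
  list(AUC = auc, AUMC = aumc)
}

# max abs deviation between a closed-form curve and a numeric profile,
# relative to the curve's peak
rel_dev <- function(curve, profile) {
  truth <- eval_exp_sum(curve, profile$times)
  max(abs(truth - profile$concentrations)) / max(abs(truth))
}

random_chain_spec <- function() {
  repeat {
    k <- sort(stats::runif(3, 0.02, 2))
    # keep rates well separated so the distinct-rate form is stable
    if (min(diff(k)) / max(k) > 0.05) break
  }
  chain_spec(k[1], k[2], k[3], dose = stats::runif(1, 10, 200),
             V = stats::runif(1, 5, 100))
}
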