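# Independent oracles and fixture builders used across the suite.

# Forward-simulated A-Ci curve in the curve CSV schema.
make_aci_curve <- function(vcmax, jmax, rd, ci = sort(co2_setpoints()),
                           constants = kinetic_constants()) {
  data.frame(driver_kind = "Ci", driver_value = ci,
             A = fvcb_assimilation(ci, vcmax, jmax, rd, constants))
}

make_aq_curve <- function(phi, amax, theta, rd, q = ppfd_levels()) {
  data.frame(driver_kind = "PPFD", driver_value = q,
             A = nrh_assimilation(q, phi, amax, theta, rd))
}

# Textbook pooled-variance Student's t: independent of stats::t.test.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}

# Dense coarse grid search over (Vcmax, Jmax, Rd) minimising the SSE of the
# min(Ac, Aj) FvCB model; brute-force alternative to the segmentation fit.
aci_grid_oracle <- function(curve, vc = seq(20, 200, length.out = 20),
                            jm = seq(40, 400, length.out = 20),
                            rd = seq(0, 4, length.out = 20),
                            constants = kinetic_constants()) {
  best <- Inf
  for (v in vc) for (j in jm) for (r in rd) {
    a <- fvcb_assimilation(curve$driver_value, v, j, r, constants)
    sse <- sum((curve$A - a)^2)
    if (sse < best) best <- sse
  }
  best
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
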