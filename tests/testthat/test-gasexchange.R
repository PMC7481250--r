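test_that("FvCB forward model matches hand-evaluated limitation rates", {
  # Rubisco-limited: Vcmax=80 with Jmax far from binding
  lim <- fvcb_limits(300, Vcmax = 80, Jmax = 500, Rd = 1)
  expect_equal(lim$A, lim$Ac)
  expect_equal(lim$Ac, 80 * (300 - 42.75) / (300 + 404.9 * (1 + 210 / 278.4)) - 1,
               tolerance = 1e-12)
  expect_equal(round(lim$Ac, 2), 19.37)
  expect_equal(lim$limitation, "Rubisco")
  # RuBP-limited: Jmax=120 with Vcmax far from binding
  lim2 <- fvcb_limits(300, Vcmax = 500, Jmax = 120, Rd = 1)
  expect_equal(lim2$A, lim2$Aj)
  expect_equal(round(lim2$Aj, 2), 19.02)
  # compensation point: both gross rates vanish
  k <- kinetic_constants()
  expect_equal(fvcb_assimilation(k$Gamma_star, 80, 130, 1.3), -1.3)
  expect_error(fvcb_limits(300, -1, 130, 1))
})

test_that("NRH forward model honours its limits and hand value", {
  expect_equal(nrh_assimilation(0, 0.05, 25, 0.7, 1.4), -1.4)
  # Blackman limit at theta = 1: min(phi*Q, Amax) - Rd
  expect_equal(nrh_assimilation(300, 0.05, 25, 1, 1), 0.05 * 300 - 1)
  expect_equal(nrh_assimilation(2000, 0.05, 25, 1, 1), 25 - 1)
  expect_equal(nrh_assimilation(500, 0.05, 25, 0.7, 1), 15.15277,
               tolerance = 1e-5)
  # continuity of the theta -> 0 branch at the switch
  expect_equal(nrh_assimilation(500, 0.05, 25, 1e-6, 1),
               nrh_assimilation(500, 0.05, 25, 9.9e-7, 1), tolerance = 1e-6)
  expect_error(nrh_assimilation(500, 0.05, 25, 1.5, 1))
})

test_that("FvCB model is non-decreasing in Ci and NRH in Q", {
  ci <- seq(0, 2000, by = 10)
  for (p in list(c(80, 130, 1), c(40, 90, 0.5), c(150, 250, 2))) {
    a <- fvcb_assimilation(ci, p[1], p[2], p[3])
    expect_true(all(diff(a) >= -1e-12))
  }
  q <- seq(0, 2500, by = 10)
  for (p in list(c(0.05, 25, 0.7, 1), c(0.08, 40, 0.95, 2))) {
    a <- nrh_assimilation(q, p[1], p[2], p[3], p[4])
    expect_true(all(diff(a) >= -1e-12))
    expect_true(all(a <= p[2] - p[4] + 1e-12))
  }
})

test_that("fit_aci recovers parameters from noise-free protocol curves", {
  curve <- make_aci_curve(75, 130, 1.2)
  fit <- fit_aci(curve)
  expect_true(fit$admissible)
  expect_lt(rel_err(fit$Vcmax, 75), 1e-3)
  expect_lt(rel_err(fit$Jmax, 130), 1e-3)
  expect_lt(rel_err(fit$Rd, 1.2), 1e-3)
  # assignment contiguous in Ci order
  st <- fit$assignment
  expect_true(all(which(st == "Rubisco") < min(c(which(st == "RuBP"), Inf))))
  expect_equal(fit$n_candidates, nrow(curve) + 1)
})

test_that("fit_aci selects the all-Rubisco assignment for a pure-Ac curve", {
  ci <- sort(co2_setpoints())
  curve <- data.frame(driver_value = ci,
                      A = 70 * (ci - 42.75) /
                        (ci + 404.9 * (1 + 210 / 278.4)) - 1)
  fit <- fit_aci(curve)
  expect_true(all(fit$assignment == "Rubisco"))
  expect_true(fit$admissible)
  expect_lt(rel_err(fit$Vcmax, 70), 1e-6)
  expect_true(is.na(fit$Jmax))
})

test_that("segmentation enumeration yields n + 1 contiguous candidates", {
  segs <- vigorlab:::.aci_segmentations(3)
  expect_length(segs, 4)
  keys <- sapply(segs, paste, collapse = ",")
  expect_setequal(keys, c("Rubisco,Rubisco,Rubisco", "RuBP,RuBP,RuBP",
                          "Rubisco,RuBP,RuBP", "Rubisco,Rubisco,RuBP"))
})

test_that("fit_aq recovers NRH parameters and Asat from noise-free curves", {
  curve <- make_aq_curve(0.055, 28, 0.75, 1.0)
  fit <- fit_aq(curve)
  expect_lt(rel_err(fit$phi, 0.055), 5e-3)
  expect_lt(rel_err(fit$Amax, 28), 5e-3)
  expect_lt(rel_err(fit$theta, 0.75), 5e-3)
  expect_lt(rel_err(fit$Asat, 27), 5e-3)
})

test_that("fit_aq recovers the cultivar Asat contrast from paired curves", {
  f1 <- fit_aq(make_aq_curve(0.055, 28, 0.75, 1.0))
  f2 <- fit_aq(make_aq_curve(0.055, 27 * 1.30 + 1.0, 0.75, 1.0))
  expect_equal(f2$Asat / f1$Asat, 1.30, tolerance = 1e-3)
})

test_that("fit_aq takes the rectangular-hyperbola branch for theta -> 0 data", {
  q <- ppfd_levels()
  a <- 0.05 * q * 30 / (0.05 * q + 30) - 1  # exact rectangular hyperbola
  fit <- fit_aq(data.frame(driver_value = q, A = a))
  expect_lte(fit$theta, 1e-3)
  expect_lt(rel_err(fit$Amax, 30), 5e-3)
})

test_that("parameter recovery holds across random physiological parameter sets", {
  set.seed(101)
  for (i in 1:15) {
    vc <- runif(1, 40, 150)
    jm <- vc * runif(1, 1.5, 2.2)
    rd <- runif(1, 0.5, 2)
    fit <- fit_aci(make_aci_curve(vc, jm, rd))
    expect_true(fit$admissible)
    expect_lt(rel_err(fit$Vcmax, vc), 5e-3)
    expect_lt(rel_err(fit$Jmax, jm), 5e-3)
  }
  for (i in 1:10) {
    phi <- runif(1, 0.04, 0.07)
    amax <- runif(1, 15, 40)
    theta <- runif(1, 0.4, 0.95)
    rd <- runif(1, 0.5, 2)
    fit <- fit_aq(make_aq_curve(phi, amax, theta, rd))
    expect_lt(rel_err(fit$Asat, amax - rd), 5e-3)
  }
})

test_that("curve validation rejects malformed inputs", {
  expect_error(fit_aci(data.frame(driver_value = 1:4, A = 1:4)), "points")
  expect_error(fit_aci(data.frame(driver_kind = "PPFD",
                                  driver_value = sort(co2_setpoints()),
                                  A = 1:13)), "driver_kind")
  expect_error(fit_aq(data.frame(driver_value = c(200, 400, 600, 800, 1000),
                                 A = 1:5)), "Q < 100")
  dup <- data.frame(driver_value = c(0, 25, 25, 400, 800), A = 1:5)
  expect_error(fit_aq(dup), "distinct")
  flat <- data.frame(driver_value = c(0, 25, 50, 400, 800), A = rep(5, 5))
  expect_error(fit_aq(flat), "degenerate")
})
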