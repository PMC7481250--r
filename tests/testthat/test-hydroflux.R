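test_that("methylene-blue areas match hand-evaluated values", {
  a <- beaker_assay(c0 = rep(0.064, 3), c1 = c(0.034, 0.054, 0.044),
                    vol = rep(0.5, 3))
  expect_equal(total_uptake_area(a), 0.022, tolerance = 1e-12)
  expect_equal(active_uptake_area(a), 0.011, tolerance = 1e-12)
  expect_equal(active_uptake_area(a) / total_uptake_area(a), 0.5)
  # no adsorption -> zero area
  b <- beaker_assay(rep(0.064, 3), rep(0.064, 3), rep(0.5, 3))
  expect_equal(total_uptake_area(b), 0)
  expect_equal(active_uptake_area(b), 0)
  expect_error(beaker_assay(rep(0.064, 3), c(0.07, 0.05, 0.05), rep(0.5, 3)),
               "assay error")
})

test_that("area equations are linear in volume and dye drop", {
  set.seed(11)
  for (i in 1:20) {
    c0 <- runif(3, 0.05, 0.08)
    c1 <- c0 * runif(3, 0.3, 1)
    v <- runif(3, 0.2, 1)
    a1 <- beaker_assay(c0, c1, v)
    a2 <- beaker_assay(c0, c1, 2 * v)
    expect_equal(total_uptake_area(a2), 2 * total_uptake_area(a1),
                 tolerance = 1e-12)
    expect_equal(active_uptake_area(a2), 2 * active_uptake_area(a1),
                 tolerance = 1e-12)
    # halving every concentration drop halves the area
    a3 <- beaker_assay(c0, c0 - (c0 - c1) / 2, v)
    expect_equal(total_uptake_area(a3), total_uptake_area(a1) / 2,
                 tolerance = 1e-12)
  }
})

test_that("uptake rates match the hand-worked mass balance", {
  p0 <- pot_sample("p1", 10, 2.0, c_nh4_mM = 1.0, c_no3_mM = 1.0, n_plants = 2)
  p1 <- pot_sample("p1", 11, 1.8, c_nh4_mM = 0.8, c_no3_mM = 0.8, n_plants = 2)
  b0 <- pot_sample("b1", 10, 2.0, c_nh4_mM = 1.0, c_no3_mM = 1.0, n_plants = 0)
  b1 <- pot_sample("b1", 11, 1.95, c_nh4_mM = 0.98, c_no3_mM = 0.98,
                   n_plants = 0)
  r <- uptake_rates(p0, p1, b0, b1)
  expect_equal(r$v_nh4, 0.2355, tolerance = 1e-12)
  expect_equal(r$v_t, 0.075, tolerance = 1e-12)
  expect_equal(r$v_total_n, r$v_nh4 + r$v_no3, tolerance = 1e-12)
  expect_false(r$suspect)
})

test_that("a treatment pot tracking the blank trajectory gives zero rates", {
  p0 <- pot_sample("p1", 10, 2.0, 1.0, 1.0, n_plants = 3)
  p1 <- pot_sample("p1", 11, 1.95, 0.98, 0.98, n_plants = 3)
  b0 <- pot_sample("b1", 10, 2.0, 1.0, 1.0, n_plants = 0)
  b1 <- pot_sample("b1", 11, 1.95, 0.98, 0.98, n_plants = 0)
  r <- uptake_rates(p0, p1, b0, b1)
  expect_identical(r$v_nh4, 0)
  expect_identical(r$v_no3, 0)
  expect_identical(r$v_t, 0)
})

test_that("conservation: Np * v_nh4 equals the blank-corrected molar loss", {
  set.seed(12)
  for (i in 1:10) {
    v1 <- runif(1, 2, 5); v2 <- v1 * runif(1, 0.7, 0.95)
    c11 <- runif(1, 0.5, 1.5); c21 <- c11 * runif(1, 0.3, 0.9)
    bv2 <- v1 * 0.98; bc21 <- c11 * 0.99 * v1 / bv2
    np <- sample(1:5, 1)
    p0 <- pot_sample("p", 10, v1, c11, c11, np)
    p1 <- pot_sample("p", 11, v2, c21, c21, np)
    b0 <- pot_sample("b", 10, v1, c11, c11, 0)
    b1 <- pot_sample("b", 11, bv2, bc21, bc21, 0)
    r <- uptake_rates(p0, p1, b0, b1)
    loss <- (v1 * c11 - v2 * c21) - (v1 * c11 - bv2 * bc21)
    expect_equal(r$v_nh4 * np, loss, tolerance = 1e-12)
  }
})

test_that("uptake precondition violations are rejected", {
  p0 <- pot_sample("p1", 10, 2, 1, 1, 2)
  p1 <- pot_sample("p2", 11, 2, 1, 1, 2)
  b0 <- pot_sample("b", 10, 2, 1, 1, 0)
  b1 <- pot_sample("b", 11, 2, 1, 1, 0)
  expect_error(uptake_rates(p0, p1, b0, b1), "pot_id")
  expect_error(uptake_rates(b0, b1, b0, b1), "at least one plant")
  expect_error(pot_sample("x", 10, 2, 1, 1, 0, is_blank = FALSE))
})

test_that("rate normalisation divides and inverts cleanly", {
  expect_equal(normalize_rate(0.24, 0.012), 20)
  expect_equal(normalize_rate(0.24, 0.6), 0.4)
  expect_equal(normalize_rate(0.24, 0.6) * 0.6, 0.24)
  expect_error(normalize_rate(0.24, 0), "positive")
})
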