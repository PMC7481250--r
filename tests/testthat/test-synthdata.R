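test_that("default config encodes the study contrasts and passes validation", {
  cfg <- default_config(42)
  expect_equal(cfg$contrast$Vcmax, 1.53)
  expect_equal(cfg$contrast$no3_uptake[["50"]], 2.99)
  expect_equal(cfg$contrast$active_area[["10"]], 3.44)
  expect_equal(cfg$contrast$biomass_ngrad[["2"]], 2.52)
  expect_length(cfg$cultivars, 2)
  expect_equal(cfg$timepoints, c(10, 25, 40, 50))
  expect_equal(cfg$n_replicates, 5L)
  expect_length(validate_config(cfg), 0)
})

test_that("config validation flags each broken invariant", {
  cfg <- default_config()
  cfg$contrast$Vcmax <- -1
  expect_length(validate_config(cfg), 1)
  cfg2 <- default_config()
  cfg2$cultivars <- c("a", "b", "c")
  expect_length(validate_config(cfg2), 1)
  cfg3 <- default_config()
  cfg3$timepoints <- c(25, 10)
  expect_length(validate_config(cfg3), 1)
  expect_error(default_config(noise_cv = c(bogus_table = 0.1)))
})

test_that("simulation is deterministic and every table is non-empty", {
  e1 <- simulate_experiment(default_config(7))
  e2 <- simulate_experiment(default_config(7))
  tables <- c("gas_exchange_curves", "pot_samples", "beaker_assays",
              "leaf_segments", "plant_records", "ngrad_records",
              "root_morphology", "seedcut_pairs", "qpcr_wells", "deg_table")
  for (tb in tables) {
    expect_identical(e1[[tb]], e2[[tb]])
    expect_gt(nrow(e1[[tb]]), 0)
  }
  e3 <- simulate_experiment(default_config(8))
  expect_false(identical(e1$seedcut_pairs, e3$seedcut_pairs))
  # blanks carry no plants
  blanks <- e1$pot_samples[e1$pot_samples$is_blank, ]
  expect_true(all(blanks$n_plants == 0))
})

test_that("gas-exchange curves are sampled on the protocol grids", {
  e <- simulate_experiment(default_config(1))
  ge <- e$gas_exchange_curves
  one_aq <- ge[ge$leaf_id == "HHZ_leaf01" & ge$driver_kind == "PPFD", ]
  expect_equal(one_aq$driver_value, ppfd_levels())
  one_aci <- ge[ge$leaf_id == "HHZ_leaf01" & ge$driver_kind == "Ci", ]
  expect_equal(one_aci$driver_value, co2_setpoints())
  expect_equal(length(co2_setpoints()), 6 + 7)
})

test_that("noise-free tables round-trip their truth values through analysis", {
  e <- simulate_experiment(default_config(5))
  tr <- e$truth
  # mass balance (pot pairs) against truth rates
  rates <- uptake_rate_table(e)
  for (cu in e$config$cultivars) for (dd in e$config$timepoints) {
    r <- rates[rates$cultivar == cu & rates$dag == dd, ]
    want <- tr$uptake[[cu]][[as.character(dd)]]
    expect_lt(max(rel_err(r$v_no3, want$v_no3)), 1e-9)
    expect_lt(max(rel_err(r$v_nh4, want$v_nh4)), 1e-9)
    expect_lt(max(rel_err(r$v_t, want$v_t)), 1e-9)
  }
  # beaker assays against truth areas
  areas <- uptake_area_table(e)
  for (cu in e$config$cultivars) for (dd in e$config$timepoints) {
    a <- areas[areas$cultivar == cu & areas$dag == dd, ]
    want <- tr$areas[[cu]][[as.character(dd)]]
    expect_lt(max(rel_err(a$total_area, want$total_area)), 1e-9)
    expect_lt(max(rel_err(a$active_area, want$active_area)), 1e-9)
  }
  # leaf segments against truth LNC / SLW
  lt <- leaf_trait_table(e)
  for (cu in e$config$cultivars) {
    l <- lt[lt$cultivar == cu, ]
    expect_lt(max(rel_err(l$LNC, tr$leaf[[cu]]$LNC)), 1e-9)
    expect_lt(max(rel_err(l$SLW, tr$leaf[[cu]]$SLW)), 1e-9)
  }
  # qPCR wells against truth fold changes
  expr <- relative_expression_table(e$qpcr_wells, calibrator_group = "HHZ")
  for (g in names(tr$qpcr_fold)) {
    got <- expr$mean_fold_change[expr$gene == g & expr$group == "9311"]
    expect_lt(rel_err(got, tr$qpcr_fold[[g]]), 1e-9)
  }
})

test_that("noise-free contrast fidelity: true ratios equal configured ratios", {
  cfg <- default_config(3)
  e <- simulate_experiment(cfg)
  tr <- e$truth
  expect_equal(tr$photosynthesis[["9311"]]$Vcmax /
                 tr$photosynthesis[["HHZ"]]$Vcmax, cfg$contrast$Vcmax)
  expect_equal(tr$photosynthesis[["9311"]]$Asat /
                 tr$photosynthesis[["HHZ"]]$Asat, cfg$contrast$Asat)
  expect_equal(tr$leaf[["9311"]]$LNC / tr$leaf[["HHZ"]]$LNC,
               cfg$contrast$LNC)
  expect_equal(tr$uptake[["9311"]][["50"]]$v_no3 /
                 tr$uptake[["HHZ"]][["50"]]$v_no3,
               cfg$contrast$no3_uptake[["50"]])
  expect_equal(tr$areas[["9311"]][["10"]]$active_area /
                 tr$areas[["HHZ"]][["10"]]$active_area,
               cfg$contrast$active_area[["10"]])
})

test_that("seed-cut pairs have the configured size and noise-free line", {
  cfg <- default_config(9)
  expect_equal(nrow(simulate_seedcut_pairs(cfg, 10)), 68)
  expect_equal(nrow(simulate_seedcut_pairs(cfg, 30)), 42)
  expect_error(simulate_seedcut_pairs(cfg, 25), "DAG")
  cfg$seedcut$residual_sd[] <- 0
  p <- simulate_seedcut_pairs(cfg, 10)
  fit <- ols_regression(p$seed_fw_g, p$biomass_g)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, cfg$seedcut$slope[["10"]], tolerance = 1e-9)
})

test_that("morphology fixture marks late branching laterals as unobserved", {
  e <- simulate_experiment(default_config(2))
  s25 <- summarize_root_morphology(e$root_morphology, 25)
  expect_false(s25$observed[s25$cultivar == "HHZ" & s25$root_class == "L_LR"])
  expect_true(s25$observed[s25$cultivar == "9311" & s25$root_class == "L_LR"])
  s10 <- summarize_root_morphology(e$root_morphology, 10)
  expect_true(all(s10$observed[s10$root_class == "seminal"]))
})

test_that("write_experiment emits stable CSVs plus truth and config JSON", {
  e <- simulate_experiment(default_config(4))
  dir <- withr::local_tempdir()
  files <- write_experiment(e, dir)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(dir, "truth.json")))
  ge <- utils::read.csv(file.path(dir, "gas_exchange_curves.csv"))
  expect_equal(nrow(ge), nrow(e$gas_exchange_curves))
  cfg2 <- read_config(file.path(dir, "config.json"))
  expect_length(validate_config(cfg2), 0)
  expect_equal(cfg2$contrast$Vcmax, 1.53)
})
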