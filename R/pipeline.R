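#' Run the full early-vigor analysis pipeline
#'
#' Orchestrates simulate -> curve fitting -> mass balance -> leaf traits ->
#' growth comparisons -> expression post-processing on a synthetic
#' two-cultivar experiment, writing one summary CSV per analysis stage and
#' a JSON run manifest. Stages run in dependency order; a stage failure
#' aborts with an error after writing a partial manifest.
#'
#' Outputs in `out_dir`: `photosynthesis_fits.csv` (per-leaf Vcmax, Jmax,
#' Rd, Asat, phi, theta), `photosynthesis_comparison.csv`,
#' `leaf_traits.csv` and `leaf_traits_comparison.csv`,
#' `uptake_rates.csv` and `uptake_comparison.csv`, `root_areas.csv`,
#' `areas_comparison.csv` and `normalized_uptake.csv`,
#' `growth_comparison.csv` (dry weights, root:shoot, N-gradient biomass),
#' `seedcut_regression.csv`, `relative_expression.csv`,
#' `nitrogen_degs.csv`, and `manifest.json`.
#'
#' @param config A `vigor_config` (see [default_config()]) or a path to a
#'   JSON config file.
#' @param out_dir Output directory, created if needed.
#' @param verbose Print per-stage progress.
#' @return Invisibly, the run manifest (list): config, seed, package
#'   version, per-stage status and row counts, output files.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  violations <- validate_config(config)
  if (length(violations) > 0)
    stop("invalid config: ", paste(violations, collapse = "; "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("vigorlab")),
    master_seed = config$rng_seed,
    config = unclass(config),
    stages = list(), files = character(0))
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    manifest$files <<- c(manifest$files, path)
    path
  }
  run_stage <- function(name, fn) {
    say("stage %s ...", name)
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)))
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  exper <- run_stage("simulate", function() simulate_experiment(config))

  fits <- run_stage("fit_curves", function() fit_all_curves(exper))
  emit("photosynthesis_fits", fits)
  photo_cmp <- run_stage("photosynthesis_comparison", function() {
    long <- .fits_long(fits)
    do.call(rbind, lapply(c("Asat", "Vcmax", "Jmax"), function(tr)
      compare_cultivars(long, tr, 50, test = config$cultivars[2],
                        ref = config$cultivars[1])))
  })
  emit("photosynthesis_comparison", photo_cmp)

  leaf <- run_stage("leaf_traits", function() leaf_trait_table(exper))
  emit("leaf_traits", leaf)
  leaf_cmp <- run_stage("leaf_comparison", function() {
    long <- .wide_to_long(leaf, c("LNC", "SLW"))
    do.call(rbind, lapply(c("LNC", "SLW"), function(tr)
      compare_cultivars(long, tr, 50, test = config$cultivars[2],
                        ref = config$cultivars[1])))
  })
  emit("leaf_traits_comparison", leaf_cmp)

  rates <- run_stage("uptake", function() uptake_rate_table(exper))
  emit("uptake_rates", rates)
  uptake_cmp <- run_stage("uptake_comparison", function() {
    long <- .wide_to_long(rates, c("v_no3", "v_nh4", "v_total_n", "v_t"))
    do.call(rbind, lapply(config$timepoints, function(dd)
      do.call(rbind, lapply(c("v_no3", "v_nh4", "v_total_n", "v_t"),
                            function(tr)
        compare_cultivars(long, tr, dd, test = config$cultivars[2],
                          ref = config$cultivars[1])))))
  })
  emit("uptake_comparison", uptake_cmp)

  areas <- run_stage("areas", function() uptake_area_table(exper))
  emit("root_areas", areas)
  area_cmp <- run_stage("areas_comparison", function() {
    long <- .wide_to_long(areas, c("total_area", "active_area",
                                   "active_to_total"))
    do.call(rbind, lapply(config$timepoints, function(dd)
      do.call(rbind, lapply(c("total_area", "active_area",
                              "active_to_total"), function(tr)
        compare_cultivars(long, tr, dd, test = config$cultivars[2],
                          ref = config$cultivars[1])))))
  })
  emit("areas_comparison", area_cmp)

  norm <- run_stage("normalized_uptake", function()
    normalized_uptake_table(rates, areas, exper$plant_records))
  emit("normalized_uptake", norm)

  growth_cmp <- run_stage("growth", function() {
    pr <- exper$plant_records
    long <- rbind(
      .wide_to_long(pr, c("shoot_dw_g", "root_dw_g")),
      data.frame(cultivar = pr$cultivar, dag = pr$dag,
                 trait = "root_shoot_ratio",
                 value = root_shoot_ratio(pr$root_dw_g, pr$shoot_dw_g)))
    main <- do.call(rbind, lapply(config$timepoints, function(dd)
      do.call(rbind, lapply(c("shoot_dw_g", "root_dw_g",
                              "root_shoot_ratio"), function(tr)
        compare_cultivars(long, tr, dd, test = config$cultivars[2],
                          ref = config$cultivars[1])))))
    ng <- exper$ngrad_records
    ng_long <- data.frame(cultivar = ng$cultivar, dag = ng$dag,
                          trait = paste0("biomass_", ng$n_level_mM, "mM"),
                          value = ng$shoot_dw_g + ng$root_dw_g)
    ngrad <- do.call(rbind, lapply(unique(ng_long$trait), function(tr)
      compare_cultivars(ng_long, tr, 40, test = config$cultivars[2],
                        ref = config$cultivars[1])))
    rbind(main, ngrad)
  })
  emit("growth_comparison", growth_cmp)

  seedcut <- run_stage("seedcut", function() {
    do.call(rbind, lapply(unique(exper$seedcut_pairs$dag), function(dd) {
      p <- exper$seedcut_pairs[exper$seedcut_pairs$dag == dd, ]
      fit <- ols_regression(p$seed_fw_g, p$biomass_g)
      data.frame(dag = dd, slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, n = fit$n)
    }))
  })
  emit("seedcut_regression", seedcut)

  expr <- run_stage("expression", function() {
    relative_expression_table(exper$qpcr_wells,
                              calibrator_group = config$cultivars[1])
  })
  emit("relative_expression", expr)

  degs <- run_stage("deg_filter", function()
    filter_nitrogen_degs(exper$deg_table))
  degs_out <- degs
  degs_out$go_terms <- vapply(degs$go_terms, paste, character(1),
                              collapse = ";")
  emit("nitrogen_degs", degs_out)

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  manifest$files <- c(manifest$files, mpath)
  say("pipeline complete: %d files", length(manifest$files))
  invisible(manifest)
}

#' Fit every gas-exchange curve in an experiment
#'
#' Applies [fit_aq()] to each A-Q curve and [fit_aci()] to each A-Ci curve,
#' one row per leaf.
#'
#' @param experiment A `vigor_experiment`, or any data.frame in the curve
#'   CSV schema (`leaf_id`, `cultivar`, `dag`, `driver_kind`,
#'   `driver_value`, `A`).
#' @param constants Kinetic constants for the A-Ci fits.
#' @return Data frame with per-leaf `Vcmax`, `Jmax`, `Rd_aci`,
#'   `aci_admissible`, `phi`, `Amax`, `theta`, `Rd_aq`, `Asat` and SSEs.
#' @export
fit_all_curves <- function(experiment, constants = kinetic_constants()) {
  curves <- if (inherits(experiment, "vigor_experiment"))
    experiment$gas_exchange_curves else experiment
  leaves <- unique(curves[, c("leaf_id", "cultivar", "dag")])
  rows <- lapply(seq_len(nrow(leaves)), function(i) {
    sub <- curves[curves$leaf_id == leaves$leaf_id[i] &
                    curves$dag == leaves$dag[i], ]
    aci <- sub[sub$driver_kind == "Ci", ]
    aq <- sub[sub$driver_kind == "PPFD", ]
    out <- data.frame(leaf_id = leaves$leaf_id[i],
                      cultivar = leaves$cultivar[i], dag = leaves$dag[i],
                      Vcmax = NA_real_, Jmax = NA_real_, Rd_aci = NA_real_,
                      sse_aci = NA_real_, aci_admissible = NA,
                      phi = NA_real_, Amax = NA_real_, theta = NA_real_,
                      Rd_aq = NA_real_, Asat = NA_real_, sse_aq = NA_real_)
    if (nrow(aci) >= 5) {
      f <- fit_aci(aci, constants)
      out$Vcmax <- f$Vcmax; out$Jmax <- f$Jmax; out$Rd_aci <- f$Rd
      out$sse_aci <- f$sse; out$aci_admissible <- f$admissible
    }
    if (nrow(aq) >= 5) {
      f <- fit_aq(aq)
      out$phi <- f$phi; out$Amax <- f$Amax; out$theta <- f$theta
      out$Rd_aq <- f$Rd; out$Asat <- f$Asat; out$sse_aq <- f$sse
    }
    out
  })
  do.call(rbind, rows)
}

#' Leaf-trait table from an experiment's leaf segments
#'
#' @param experiment A `vigor_experiment` or a leaf-segment data.frame
#'   (`leaf_id`, `cultivar`, `dag`, `width_cm`, `dry_mass_g`,
#'   `n_fraction`).
#' @return The input plus `LNC` (g m^-2) and `SLW` (g m^-2) columns.
#' @export
leaf_trait_table <- function(experiment) {
  seg <- if (inherits(experiment, "vigor_experiment"))
    experiment$leaf_segments else experiment
  seg$LNC <- leaf_nitrogen_content(seg$n_fraction, seg$dry_mass_g,
                                   seg$width_cm)
  seg$SLW <- specific_leaf_weight(seg$dry_mass_g, seg$width_cm)
  seg
}

#' Per-pot uptake rates from an experiment's pot samples
#'
#' Pairs each treatment pot's consecutive-day samples with the same-day
#' blank pair and applies the blank-corrected mass balance.
#'
#' @param experiment A `vigor_experiment` or a pot-sample data.frame.
#' @return Data frame of per-pot rates with cultivar and dag.
#' @export
uptake_rate_table <- function(experiment) {
  pots <- if (inherits(experiment, "vigor_experiment"))
    experiment$pot_samples else experiment
  treat <- pots[!pots$is_blank, ]
  blank <- pots[pots$is_blank, ]
  ids <- unique(treat$pot_id)
  rows <- lapply(ids, function(id) {
    p <- treat[treat$pot_id == id, ]
    p <- p[order(p$day), ]
    b <- blank[blank$dag == p$dag[1], ]
    b <- b[order(b$day), ]
    r <- uptake_rates(p[1, ], p[2, ], b[1, ], b[2, ])
    r$cultivar <- p$cultivar[1]
    r$dag <- p$dag[1]
    # keep the ion naming of the source columns
    data.frame(pot_id = r$pot_id, cultivar = r$cultivar, dag = r$dag,
               v_nh4 = r$v_nh4, v_no3 = r$v_no3, v_total_n = r$v_total_n,
               v_t = r$v_t, suspect = r$suspect)
  })
  do.call(rbind, rows)
}

#' Per-plant root uptake areas from an experiment's beaker assays
#'
#' @param experiment A `vigor_experiment` or a beaker-assay data.frame in
#'   long beaker format (`plant_id`, `cultivar`, `dag`, `beaker`, `c0_gL`,
#'   `c1_gL`, `vol_L`).
#' @return Data frame with per-plant `total_area`, `active_area` and
#'   `active_to_total`.
#' @export
uptake_area_table <- function(experiment) {
  assays <- if (inherits(experiment, "vigor_experiment"))
    experiment$beaker_assays else experiment
  ids <- unique(assays[, c("plant_id", "cultivar", "dag")])
  rows <- lapply(seq_len(nrow(ids)), function(i) {
    sub <- assays[assays$plant_id == ids$plant_id[i], ]
    sub <- sub[order(sub$beaker), ]
    a <- beaker_assay(sub$c0_gL, sub$c1_gL, sub$vol_L,
                      plant_id = ids$plant_id[i])
    tot <- total_uptake_area(a)
    act <- active_uptake_area(a)
    data.frame(plant_id = ids$plant_id[i], cultivar = ids$cultivar[i],
               dag = ids$dag[i], total_area = tot, active_area = act,
               active_to_total = if (tot > 0) act / tot else NA_real_)
  })
  do.call(rbind, rows)
}

#' Group-mean uptake rates normalised by active area and root dry weight
#'
#' @param rates Output of [uptake_rate_table()].
#' @param areas Output of [uptake_area_table()].
#' @param plant_records Plant dry-weight records (`cultivar`, `dag`,
#'   `root_dw_g`).
#' @return Per cultivar x dag group means of v(NO3-), v(NH4+) and total N
#'   on an active-area basis and a root dry-weight basis.
#' @export
normalized_uptake_table <- function(rates, areas, plant_records) {
  grid <- unique(rates[, c("cultivar", "dag")])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cu <- grid$cultivar[i]; dd <- grid$dag[i]
    r <- rates[rates$cultivar == cu & rates$dag == dd, ]
    ar <- areas[areas$cultivar == cu & areas$dag == dd, ]
    pw <- plant_records[plant_records$cultivar == cu &
                          plant_records$dag == dd, ]
    act <- mean(ar$active_area)
    rdw <- mean(pw$root_dw_g)
    data.frame(
      cultivar = cu, dag = dd,
      v_no3_per_area = normalize_rate(mean(r$v_no3), act),
      v_nh4_per_area = normalize_rate(mean(r$v_nh4), act),
      v_total_n_per_area = normalize_rate(mean(r$v_total_n), act),
      v_no3_per_rdw = normalize_rate(mean(r$v_no3), rdw),
      v_nh4_per_rdw = normalize_rate(mean(r$v_nh4), rdw),
      v_total_n_per_rdw = normalize_rate(mean(r$v_total_n), rdw))
  })
  do.call(rbind, rows)
}

.fits_long <- function(fits) {
  do.call(rbind, lapply(c("Asat", "Vcmax", "Jmax"), function(tr) {
    data.frame(cultivar = fits$cultivar, dag = fits$dag, trait = tr,
               value = fits[[tr]])
  }))
}

.wide_to_long <- function(df, traits) {
  do.call(rbind, lapply(traits, function(tr) {
    data.frame(cultivar = df$cultivar, dag = df$dag, trait = tr,
               value = df[[tr]])
  }))
}
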