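#' Default configuration for a synthetic two-cultivar experiment
#'
#' Builds the configuration that drives [simulate_experiment()]. The
#' cultivar contrast ratios (9311 over HHZ) encode the study's reported
#' percent differences as `1 + percent/100`: 30/53/34% for Asat/Vcmax/Jmax,
#' 26% LNC, 28% SLW, 24% leaf width, 199% NO3- and 92% NH4+ uptake at
#' 50 DAG, 77% total and 244% active root uptake area at 10 DAG (87%/126%
#' at 50 DAG), shoot dry weight 44/49/79/37% and root dry weight
#' 67/78/84/22% at 10/25/40/50 DAG, and 40-DAG biomass 37/84/127/152%
#' higher at 0.1/0.5/1/2 mM NH4NO3. Ratios at timepoints without a printed
#' percent are plausible interior defaults. HHZ absolute baselines are
#' documented arbitrary constants; only the ratios are study-anchored.
#'
#' The seed-cutting arm draws seed fresh weights uniformly and derives its
#' residual SD from the target pooled R-squared (0.86 at 10 DAG, 0.78 at
#' 30 DAG) via `sd_res = slope * sd_x * sqrt(1/R2 - 1)`.
#'
#' @param rng_seed Master integer seed; every table uses an independent
#'   substream derived from it.
#' @param n_replicates Replicates per cultivar per timepoint (default 5;
#'   the nitrogen-gradient arm uses `n_replicates_ngrad = 9`).
#' @param noise_cv Named coefficients of variation per table (all 0 by
#'   default, giving deterministic fixtures); names as in the default.
#' @return A list of class `vigor_config`.
#' @export
default_config <- function(rng_seed = 1L, n_replicates = 5L,
                           noise_cv = NULL) {
  cv <- c(gas_exchange = 0, pot_samples = 0, beaker_assays = 0,
          leaf_segments = 0, plant_records = 0, qpcr = 0,
          root_morphology = 0)
  if (!is.null(noise_cv)) {
    stopifnot(all(names(noise_cv) %in% names(cv)))
    cv[names(noise_cv)] <- noise_cv
  }
  tp <- c(10, 25, 40, 50)
  seedcut <- list(
    n_pairs = c("10" = 68L, "30" = 42L),
    slope = c("10" = 2, "30" = 20),
    intercept = c("10" = 0.005, "30" = 0.05),
    seed_fw_range_g = c(0.005, 0.025),
    target_r2 = c("10" = 0.86, "30" = 0.78))
  sd_x <- diff(seedcut$seed_fw_range_g) / sqrt(12)
  seedcut$residual_sd <- seedcut$slope * sd_x *
    sqrt(1 / seedcut$target_r2 - 1)

  cfg <- list(
    rng_seed = as.integer(rng_seed),
    n_replicates = as.integer(n_replicates),
    n_replicates_ngrad = 9L,
    timepoints = tp,
    cultivars = c("HHZ", "9311"),
    n_levels_mM = c(0.1, 0.5, 1, 2),
    contrast = list(
      Asat = 1.30, Vcmax = 1.53, Jmax = 1.34,
      LNC = 1.26, SLW = 1.28, leaf_width = 1.24,
      no3_uptake = c("10" = 1.40, "25" = 1.80, "40" = 2.40, "50" = 2.99),
      nh4_uptake = c("10" = 0.90, "25" = 1.30, "40" = 1.60, "50" = 1.92),
      water_uptake = c("10" = 1.10, "25" = 1.30, "40" = 1.50, "50" = 1.70),
      total_area = c("10" = 1.77, "25" = 1.80, "40" = 1.85, "50" = 1.87),
      active_area = c("10" = 3.44, "25" = 3.00, "40" = 2.60, "50" = 2.26),
      shoot_dw = c("10" = 1.44, "25" = 1.49, "40" = 1.79, "50" = 1.37),
      root_dw = c("10" = 1.67, "25" = 1.78, "40" = 1.84, "50" = 1.22),
      biomass_ngrad = c("0.1" = 1.37, "0.5" = 1.84, "1" = 2.27, "2" = 2.52)),
    hhz_baselines = list(
      fvcb = c(Vcmax = 80, Jmax = 130, Rd = 1.0),
      nrh = c(phi = 0.055, Amax = 28, theta = 0.75, Rd = 1.0),
      lnc_g_m2 = 1.2, slw_g_m2 = 40, leaf_width_cm = 1.0,
      no3_uptake = c("10" = 0.02, "25" = 0.08, "40" = 0.16, "50" = 0.25),
      nh4_uptake = c("10" = 0.025, "25" = 0.09, "40" = 0.15, "50" = 0.20),
      water_uptake = c("10" = 0.01, "25" = 0.05, "40" = 0.15, "50" = 0.30),
      total_area_m2 = c("10" = 0.004, "25" = 0.012, "40" = 0.02,
                        "50" = 0.03),
      active_area_m2 = c("10" = 0.0012, "25" = 0.005, "40" = 0.009,
                         "50" = 0.012),
      shoot_dw_g = c("10" = 0.02, "25" = 0.15, "40" = 0.8, "50" = 2.0),
      root_dw_g = c("10" = 0.008, "25" = 0.05, "40" = 0.25, "50" = 0.5),
      biomass_ngrad_g = c("0.1" = 0.4, "0.5" = 0.8, "1" = 1.05, "2" = 1.2)),
    noise_cv = cv,
    seedcut = seedcut,
    pot = list(volume_L = 4, n_plants = 3L, evap_frac = 0.02,
               n_loss_frac = 0.01),
    beaker = list(c0_gL = 0.064, vol_L = 0.5),
    qpcr_fold = c(OsNRT2.1 = 4.0, OsNRT2.4 = 3.5, OsNIA1 = 2.5,
                  OsNR1 = 2.2, OsAlaAT2 = 1.8, OsAlaAT4 = 0.4))
  class(cfg) <- "vigor_config"
  violations <- validate_config(cfg)
  if (length(violations) > 0)
    stop("invalid config: ", paste(violations, collapse = "; "))
  cfg
}

#' Validate an experiment configuration
#'
#' @param config A `vigor_config` list (or a path to a JSON file written by
#'   [write_experiment()] / [jsonlite::write_json()]).
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(length(config$cultivars) == 2, "exactly two cultivars required")
  chk(all(diff(config$timepoints) > 0), "timepoints must be strictly increasing")
  chk(config$n_replicates >= 1, "n_replicates must be at least 1")
  chk(all(unlist(config$contrast) > 0), "all contrast ratios must be positive")
  chk(all(unlist(config$hhz_baselines) > 0), "all baselines must be positive")
  chk(all(config$noise_cv >= 0), "noise CVs must be non-negative")
  chk(all(config$n_levels_mM > 0), "nitrogen levels must be positive")
  chk(all(config$seedcut$residual_sd >= 0), "residual SD must be non-negative")
  v
}

#' @rdname validate_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # restore names dropped by JSON round-trip of scalar-named vectors
  class(cfg) <- "vigor_config"
  cfg
}

# Independent RNG substream per output table so adding a table never
# perturbs the others. Keeps derived seeds in 32-bit integer range.
.substream <- function(master, idx) {
  s <- (as.double(master) * 7919 + idx * 104729) %% 2147483647
  set.seed(as.integer(s))
}

# Multiplicative Gaussian noise, CV-parameterised, truncated at zero
# (positive-valued physiological measurements).
.noisy <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(x * stats::rnorm(length(x), mean = 1, sd = cv), 0)
}

.ratio_at <- function(contrast_entry, dag) {
  if (length(contrast_entry) == 1) return(unname(contrast_entry))
  unname(contrast_entry[[as.character(dag)]])
}

.cultivar_ratio <- function(config, cultivar, trait, dag = NULL) {
  if (cultivar == config$cultivars[1]) return(1)
  entry <- config$contrast[[trait]]
  if (is.null(dag)) unname(entry) else .ratio_at(entry, dag)
}

#' Simulate a complete synthetic two-cultivar experiment
#'
#' Generates every measured table of the study design from known truth
#' values via the forward models of the analysis modules: gas-exchange
#' curves by FvCB and non-rectangular-hyperbola forward evaluation on the
#' protocol grids, beaker assays by inverting the methylene-blue area
#' equations, pot samples by inverting the blank-corrected mass balances
#' (with a nonzero abiotic loss term so the blank correction is exercised),
#' and leaf segments by inverting the LNC equation. Multiplicative Gaussian
#' noise at the configured CVs (default 0) is applied to measured values;
#' the returned `truth` element maps every generated quantity to its
#' noise-free true value. Identical configuration (including seed) gives
#' identical output.
#'
#' @param config A `vigor_config` from [default_config()].
#' @return A list of class `vigor_experiment` with elements
#'   `gas_exchange_curves`, `pot_samples`, `beaker_assays`,
#'   `leaf_segments`, `plant_records`, `ngrad_records`,
#'   `root_morphology`, `seedcut_pairs`, `qpcr_wells`, `deg_table`,
#'   `truth` and `config`.
#' @export
simulate_experiment <- function(config = default_config()) {
  violations <- validate_config(config)
  if (length(violations) > 0)
    stop("invalid config: ", paste(violations, collapse = "; "))

  truth <- list()
  out <- list(config = config)

  ge <- .sim_gas_exchange(config)
  out$gas_exchange_curves <- ge$table
  truth$photosynthesis <- ge$truth

  pots <- .sim_pot_samples(config)
  out$pot_samples <- pots$table
  truth$uptake <- pots$truth

  bk <- .sim_beaker_assays(config)
  out$beaker_assays <- bk$table
  truth$areas <- bk$truth

  lf <- .sim_leaf_segments(config)
  out$leaf_segments <- lf$table
  truth$leaf <- lf$truth

  pr <- .sim_plant_records(config)
  out$plant_records <- pr$table
  out$ngrad_records <- pr$ngrad
  truth$growth <- pr$truth

  rm_ <- .sim_root_morphology(config)
  out$root_morphology <- rm_$table
  truth$root_morphology <- rm_$truth

  sc10 <- simulate_seedcut_pairs(config, 10)
  sc30 <- simulate_seedcut_pairs(config, 30)
  out$seedcut_pairs <- rbind(sc10, sc30)
  truth$seedcut <- config$seedcut

  qp <- .sim_qpcr(config)
  out$qpcr_wells <- qp$table
  truth$qpcr_fold <- qp$truth

  dg <- .sim_deg_table(config)
  out$deg_table <- dg$table
  truth$deg <- dg$truth

  out$truth <- truth
  class(out) <- "vigor_experiment"
  out
}

# --- gas exchange ---------------------------------------------------------

.sim_gas_exchange <- function(config) {
  .substream(config$rng_seed, 1)
  cv <- config$noise_cv[["gas_exchange"]]
  fv <- config$hhz_baselines$fvcb
  nr <- config$hhz_baselines$nrh
  rows <- list()
  truth <- list()
  for (cultivar in config$cultivars) {
    vcmax <- fv[["Vcmax"]] * .cultivar_ratio(config, cultivar, "Vcmax")
    jmax <- fv[["Jmax"]] * .cultivar_ratio(config, cultivar, "Jmax")
    rd <- fv[["Rd"]]
    asat_hhz <- nr[["Amax"]] - nr[["Rd"]]
    asat <- asat_hhz * .cultivar_ratio(config, cultivar, "Asat")
    amax <- asat + nr[["Rd"]]
    truth[[cultivar]] <- list(Vcmax = vcmax, Jmax = jmax, Rd = rd,
                              phi = nr[["phi"]], Amax = amax,
                              theta = nr[["theta"]], Asat = asat)
    for (rep in seq_len(config$n_replicates)) {
      ci <- co2_setpoints()
      a_ci <- fvcb_assimilation(ci, vcmax, jmax, rd)
      rows[[length(rows) + 1L]] <- data.frame(
        leaf_id = sprintf("%s_leaf%02d", cultivar, rep),
        cultivar = cultivar, dag = 50, replicate = rep,
        driver_kind = "Ci", driver_value = ci, A = .noisy(a_ci, cv))
      q <- ppfd_levels()
      a_q <- nrh_assimilation(q, nr[["phi"]], amax, nr[["theta"]], nr[["Rd"]])
      rows[[length(rows) + 1L]] <- data.frame(
        leaf_id = sprintf("%s_leaf%02d", cultivar, rep),
        cultivar = cultivar, dag = 50, replicate = rep,
        driver_kind = "PPFD", driver_value = q, A = .noisy(a_q, cv))
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

# --- pot samples ----------------------------------------------------------

.sim_pot_samples <- function(config) {
  .substream(config$rng_seed, 2)
  cv <- config$noise_cv[["pot_samples"]]
  pot <- config$pot
  bl <- config$hhz_baselines
  rows <- list()
  truth <- list()
  v1 <- pot$volume_L
  c0 <- 1  # fresh solution: 1 mM NH4NO3 -> 1 mM each ion
  for (dag in config$timepoints) {
    dag_key <- as.character(dag)
    # blank pair: abiotic losses only
    loss_mol <- pot$n_loss_frac * v1 * c0
    loss_vol <- pot$evap_frac * v1
    v2b <- v1 - loss_vol
    c2b <- (v1 * c0 - loss_mol) / v2b
    rows[[length(rows) + 1L]] <- data.frame(
      pot_id = paste0("blank_", dag), cultivar = NA_character_, dag = dag,
      day = dag, is_blank = TRUE, n_plants = 0L,
      volume_L = v1, c_nh4_mM = c0, c_no3_mM = c0)
    rows[[length(rows) + 1L]] <- data.frame(
      pot_id = paste0("blank_", dag), cultivar = NA_character_, dag = dag,
      day = dag + 1, is_blank = TRUE, n_plants = 0L,
      volume_L = .noisy(v2b, cv), c_nh4_mM = .noisy(c2b, cv),
      c_no3_mM = .noisy(c2b, cv))
    for (cultivar in config$cultivars) {
      v_no3 <- bl$no3_uptake[[dag_key]] *
        .cultivar_ratio(config, cultivar, "no3_uptake", dag)
      v_nh4 <- bl$nh4_uptake[[dag_key]] *
        .cultivar_ratio(config, cultivar, "nh4_uptake", dag)
      v_t <- bl$water_uptake[[dag_key]] *
        .cultivar_ratio(config, cultivar, "water_uptake", dag)
      truth[[cultivar]][[dag_key]] <- list(v_no3 = v_no3, v_nh4 = v_nh4,
                                           v_t = v_t,
                                           v_total_n = v_no3 + v_nh4)
      np <- pot$n_plants
      v2 <- v1 - loss_vol - np * v_t
      if (v2 <= 0) stop("pot volume depleted; lower uptake baselines")
      c2_nh4 <- (v1 * c0 - loss_mol - np * v_nh4) / v2
      c2_no3 <- (v1 * c0 - loss_mol - np * v_no3) / v2
      if (c2_nh4 < 0 || c2_no3 < 0)
        stop("pot nutrients depleted; lower uptake baselines")
      for (rep in seq_len(config$n_replicates)) {
        pid <- sprintf("%s_%d_pot%02d", cultivar, dag, rep)
        rows[[length(rows) + 1L]] <- data.frame(
          pot_id = pid, cultivar = cultivar, dag = dag, day = dag,
          is_blank = FALSE, n_plants = np,
          volume_L = v1, c_nh4_mM = c0, c_no3_mM = c0)
        rows[[length(rows) + 1L]] <- data.frame(
          pot_id = pid, cultivar = cultivar, dag = dag, day = dag + 1,
          is_blank = FALSE, n_plants = np,
          volume_L = .noisy(v2, cv), c_nh4_mM = .noisy(c2_nh4, cv),
          c_no3_mM = .noisy(c2_no3, cv))
      }
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

# --- beaker assays --------------------------------------------------------

.sim_beaker_assays <- function(config) {
  .substream(config$rng_seed, 3)
  cv <- config$noise_cv[["beaker_assays"]]
  c0 <- config$beaker$c0_gL
  vol <- config$beaker$vol_L
  bl <- config$hhz_baselines
  rows <- list()
  truth <- list()
  for (dag in config$timepoints) {
    dag_key <- as.character(dag)
    for (cultivar in config$cultivars) {
      total <- bl$total_area_m2[[dag_key]] *
        .cultivar_ratio(config, cultivar, "total_area", dag)
      active <- bl$active_area_m2[[dag_key]] *
        .cultivar_ratio(config, cultivar, "active_area", dag)
      truth[[cultivar]][[dag_key]] <- list(total_area = total,
                                           active_area = active,
                                           active_to_total = active / total)
      # invert the area equations: split the total-dye drop evenly over
      # beakers 1 and 2; beaker 3 carries the active-area drop
      drop12 <- total / 1.1 / (2 * vol)
      drop3 <- active / 1.1 / vol
      if (drop12 > c0 || drop3 > c0)
        stop("methylene-blue assay infeasible: area too large for c0 * vol")
      for (rep in seq_len(config$n_replicates)) {
        c1 <- c(c0 - drop12, c0 - drop12, c0 - drop3)
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = sprintf("%s_%d_plant%02d", cultivar, dag, rep),
          cultivar = cultivar, dag = dag, beaker = 1:3,
          c0_gL = c0, c1_gL = pmin(.noisy(c1, cv), c0), vol_L = vol)
      }
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

# --- leaf segments --------------------------------------------------------

.sim_leaf_segments <- function(config) {
  .substream(config$rng_seed, 4)
  cv <- config$noise_cv[["leaf_segments"]]
  bl <- config$hhz_baselines
  rows <- list()
  truth <- list()
  for (cultivar in config$cultivars) {
    lnc <- bl$lnc_g_m2 * .cultivar_ratio(config, cultivar, "LNC")
    slw <- bl$slw_g_m2 * .cultivar_ratio(config, cultivar, "SLW")
    width <- bl$leaf_width_cm * .cultivar_ratio(config, cultivar, "leaf_width")
    c_n <- lnc / slw
    mass <- slw * (10 * width * 1e-4)  # invert the LNC/SLW area relation
    truth[[cultivar]] <- list(LNC = lnc, SLW = slw, width_cm = width,
                              n_fraction = c_n)
    for (rep in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        leaf_id = sprintf("%s_leaf%02d", cultivar, rep),
        cultivar = cultivar, dag = 50,
        width_cm = .noisy(width, cv), dry_mass_g = .noisy(mass, cv),
        n_fraction = .noisy(c_n, cv))
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

# --- plant records (dry weights + nitrogen gradient) ----------------------

.sim_plant_records <- function(config) {
  .substream(config$rng_seed, 5)
  cv <- config$noise_cv[["plant_records"]]
  bl <- config$hhz_baselines
  rows <- list()
  ngrad <- list()
  truth <- list(main = list(), ngrad = list())
  for (dag in config$timepoints) {
    dag_key <- as.character(dag)
    for (cultivar in config$cultivars) {
      shoot <- bl$shoot_dw_g[[dag_key]] *
        .cultivar_ratio(config, cultivar, "shoot_dw", dag)
      root <- bl$root_dw_g[[dag_key]] *
        .cultivar_ratio(config, cultivar, "root_dw", dag)
      truth$main[[cultivar]][[dag_key]] <-
        list(shoot_dw = shoot, root_dw = root,
             root_shoot_ratio = root / shoot)
      for (rep in seq_len(config$n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cultivar = cultivar, dag = dag, replicate = rep,
          shoot_dw_g = .noisy(shoot, cv), root_dw_g = .noisy(root, cv))
      }
    }
  }
  root_frac <- 0.2  # shoot/root split of total biomass in the gradient arm
  for (lvl in config$n_levels_mM) {
    key <- as.character(lvl)
    for (cultivar in config$cultivars) {
      total <- bl$biomass_ngrad_g[[key]] *
        (if (cultivar == config$cultivars[1]) 1
         else config$contrast$biomass_ngrad[[key]])
      truth$ngrad[[cultivar]][[key]] <- list(biomass = total)
      for (rep in seq_len(config$n_replicates_ngrad)) {
        ngrad[[length(ngrad) + 1L]] <- data.frame(
          cultivar = cultivar, dag = 40, n_level_mM = lvl, replicate = rep,
          shoot_dw_g = .noisy(total * (1 - root_frac), cv),
          root_dw_g = .noisy(total * root_frac, cv))
      }
    }
  }
  list(table = do.call(rbind, rows), ngrad = do.call(rbind, ngrad),
       truth = truth)
}

# --- root morphology ------------------------------------------------------

.sim_root_morphology <- function(config) {
  .substream(config$rng_seed, 6)
  cv <- config$noise_cv[["root_morphology"]]
  base_len <- c(seminal = 15, crown = 10, L_LR = 2, S_LR = 0.8,
                secondary_LR = 0.3)
  base_diam <- c(seminal = 0.45, crown = 0.5, L_LR = 0.15, S_LR = 0.1,
                 secondary_LR = 0.08)
  base_count <- c(seminal = 1, crown = 6, L_LR = 15, S_LR = 50,
                  secondary_LR = 80)
  rows <- list()
  truth <- list()
  for (dag in config$timepoints) {
    growth <- sqrt(dag / 10)
    for (cultivar in config$cultivars) {
      mult <- if (cultivar == config$cultivars[1]) 1 else 1.2
      for (cls in names(base_len)) {
        # one cultivar develops branching L-type laterals later: none at
        # 25 DAG on the reference cultivar (the figures mark this cell
        # "not observed")
        if (cls == "L_LR" && cultivar == config$cultivars[1] && dag == 25)
          next
        len <- base_len[[cls]] * growth * mult
        diam <- base_diam[[cls]] * mult
        cnt <- round(base_count[[cls]] * growth)
        truth[[cultivar]][[as.character(dag)]][[cls]] <-
          list(length_cm = len, diameter_mm = diam, count = cnt)
        for (rep in seq_len(config$n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            plant_id = sprintf("%s_%d_plant%02d", cultivar, dag, rep),
            cultivar = cultivar, dag = dag, root_class = cls,
            length_cm = .noisy(len, cv), diameter_mm = .noisy(diam, cv),
            count = cnt)
        }
      }
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

#' Simulate seed-cutting pairs
#'
#' Endosperm is cut from germinated seeds, the remaining seed is weighed,
#' and plant biomass is measured later. Pairs are generated from the linear
#' model `biomass = slope * seed_fw + intercept + N(0, residual_sd)`, with
#' seed fresh weights uniform over the configured range and the residual SD
#' calibrated to the target pooled R-squared.
#'
#' @param config A `vigor_config`.
#' @param dag Harvest timepoint, 10 or 30.
#' @return Data frame with `dag`, `seed_fw_g`, `biomass_g` (n = 68 pairs at
#'   10 DAG, 42 at 30 DAG by default).
#' @export
simulate_seedcut_pairs <- function(config, dag) {
  key <- as.character(dag)
  sc <- config$seedcut
  if (!key %in% names(sc$n_pairs))
    stop("seed-cut harvests exist only at DAG ", paste(names(sc$n_pairs),
                                                       collapse = ", "))
  .substream(config$rng_seed, 7 + as.integer(dag))
  n <- sc$n_pairs[[key]]
  x <- stats::runif(n, sc$seed_fw_range_g[1], sc$seed_fw_range_g[2])
  y <- sc$slope[[key]] * x + sc$intercept[[key]] +
    stats::rnorm(n, 0, sc$residual_sd[[key]])
  data.frame(dag = dag, seed_fw_g = x, biomass_g = pmax(y, 0))
}

# --- qPCR -----------------------------------------------------------------

.sim_qpcr <- function(config) {
  .substream(config$rng_seed, 8)
  cv <- config$noise_cv[["qpcr"]]
  folds <- config$qpcr_fold
  cal <- config$cultivars[1]
  other <- config$cultivars[2]
  ct_ref <- 20
  rows <- list()
  for (i in seq_along(folds)) {
    gene <- names(folds)[i]
    ct_cal <- 23 + i * 0.5
    ct_oth <- ct_cal - log2(folds[[i]])  # invert 2^-ddCt
    for (rep in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = cal, replicate = rep,
        ct = .noisy(ct_cal, cv))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = other, replicate = rep,
        ct = .noisy(ct_oth, cv))
    }
  }
  for (rep in 1:3) {
    for (g in c(cal, other)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = "OsActin1", group = g, replicate = rep,
        ct = .noisy(ct_ref, cv))
    }
  }
  list(table = do.call(rbind, rows), truth = as.list(folds))
}

# --- DEG table ------------------------------------------------------------

.sim_deg_table <- function(config) {
  .substream(config$rng_seed, 9)
  up <- c("OsNRT2.1", "OsNRT2.4", "OsNR1", "OsNIA1", "OsAlaAT2", "OsNAAT5",
          "Os06g0548000", "Os01g0760600", "Os02g0236000", "Os03g0707900")
  down <- c("RCS1", "OsAlaAT4", "ARE1", "AMI1", "AMI2")
  n_go <- c("nitrate transmembrane transport", "nitrogen compound metabolic process",
            "ammonia assimilation cycle", "response to nitrate",
            "nitrate assimilation")
  other_go <- c("protein phosphorylation", "lipid metabolic process",
                "cell wall organization", "response to oxidative stress")
  mk <- function(genes, lfc_sign, padj, go_pool) {
    data.frame(
      gene_id = genes,
      log2fc = lfc_sign * stats::runif(length(genes), 0.8, 3.5),
      padj = padj,
      go_terms = vapply(seq_along(genes), function(i) {
        paste(sample(go_pool, 2), collapse = ";")
      }, character(1)))
  }
  sig_n <- rbind(
    mk(up, +1, stats::runif(length(up), 1e-8, 1e-3), n_go),
    mk(down, -1, stats::runif(length(down), 1e-8, 1e-3), n_go))
  # decoys: significant without nitrogen GO, and nitrogen GO without
  # significance
  decoy_sig <- mk(sprintf("Os%02dg%07d", 1:6, 1000000 + 1:6), +1,
                  stats::runif(6, 1e-6, 0.01), other_go)
  decoy_ns <- mk(sprintf("Os%02dg%07d", 1:4, 2000000 + 1:4), +1,
                 stats::runif(4, 0.2, 0.9), n_go)
  tab <- rbind(sig_n, decoy_sig, decoy_ns)
  tab <- tab[sample(nrow(tab)), ]
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(n_qualifying = length(up) + length(down),
                    n_up = length(up), up_genes = up, down_genes = down))
}

#' Write a synthetic experiment to disk
#'
#' Emits one UTF-8 comma-separated file per table (stable, documented
#' filenames: `gas_exchange_curves.csv`, `pot_samples.csv`,
#' `beaker_assays.csv`, `leaf_segments.csv`, `plant_records.csv`,
#' `ngrad_records.csv`, `root_morphology.csv`, `seedcut_pairs.csv`,
#' `qpcr_wells.csv`, `deg_table.csv`) plus `truth.json` and `config.json`.
#'
#' @param experiment A `vigor_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "vigor_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("gas_exchange_curves", "pot_samples", "beaker_assays",
              "leaf_segments", "plant_records", "ngrad_records",
              "root_morphology", "seedcut_pairs", "qpcr_wells", "deg_table")
  files <- character(0)
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(experiment[[tb]], path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, path)
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(experiment$truth, tp, auto_unbox = TRUE, digits = NA)
  cp <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(experiment$config), cp, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, tp, cp)
  invisible(files)
}

#' @export
print.vigor_experiment <- function(x, ...) {
  cat("Synthetic two-cultivar experiment\n")
  cat(sprintf("  cultivars: %s; timepoints: %s DAG; n = %d\n",
              paste(x$config$cultivars, collapse = ", "),
              paste(x$config$timepoints, collapse = "/"),
              x$config$n_replicates))
  for (tb in c("gas_exchange_curves", "pot_samples", "beaker_assays",
               "leaf_segments", "plant_records", "ngrad_records",
               "root_morphology", "seedcut_pairs", "qpcr_wells",
               "deg_table")) {
    cat(sprintf("  %-20s %5d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}
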