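#' Root uptake areas from the methylene-blue three-beaker assay
#'
#' Roots are dipped successively in three beakers of methylene-blue solution.
#' Beakers 1 and 2 together saturate the whole surface with a monolayer, so
#' the total uptake area is
#' \deqn{[(C_1^0 - C_1^1) V_1 + (C_2^0 - C_2^1) V_2] \times 1.1;}
#' dye removed from beaker 3 can only be absorbed by surface with ongoing
#' uptake activity, giving the active uptake area
#' \deqn{(C_3^0 - C_3^1) V_3 \times 1.1.}
#' The 1.1 constant converts adsorbed dye mass to surface area (classically
#' 1.1 m^2 per mg methylene blue); concentrations are in g L^-1 and volumes
#' in L, and downstream results use only ratios and normalisations, where
#' the absolute scale cancels.
#'
#' @param assay A beaker assay: list or one-row data.frame with numeric
#'   length-3 fields `c0` (initial concentrations, g L^-1), `c1`
#'   (post-staining concentrations, g L^-1) and `vol` (volumes, L), indexed
#'   by beaker; see [beaker_assay()].
#' @return Area (same relative units for both operations).
#' @export
#' @examples
#' a <- beaker_assay(c0 = rep(0.064, 3), c1 = c(0.034, 0.054, 0.044),
#'                   vol = rep(0.5, 3))
#' total_uptake_area(a)   # 0.022
#' active_uptake_area(a)  # 0.011
total_uptake_area <- function(assay) {
  assay <- .check_assay(assay)
  ((assay$c0[1] - assay$c1[1]) * assay$vol[1] +
     (assay$c0[2] - assay$c1[2]) * assay$vol[2]) * 1.1
}

#' @rdname total_uptake_area
#' @export
active_uptake_area <- function(assay) {
  assay <- .check_assay(assay)
  (assay$c0[3] - assay$c1[3]) * assay$vol[3] * 1.1
}

#' Construct a methylene-blue beaker assay record
#'
#' @param c0,c1 Initial and post-staining dye concentrations (g L^-1),
#'   length 3 (beakers 1-3).
#' @param vol Solution volumes (L), length 3.
#' @param plant_id Optional identifier.
#' @return A list of class `beaker_assay`.
#' @export
beaker_assay <- function(c0, c1, vol, plant_id = NA_character_) {
  out <- structure(list(c0 = as.numeric(c0), c1 = as.numeric(c1),
                        vol = as.numeric(vol), plant_id = plant_id),
                   class = "beaker_assay")
  .check_assay(out)
}

.check_assay <- function(assay) {
  stopifnot(length(assay$c0) == 3, length(assay$c1) == 3,
            length(assay$vol) == 3)
  if (any(assay$vol <= 0)) stop("beaker volumes must be positive")
  if (any(assay$c1 < 0) || any(assay$c0 < 0))
    stop("concentrations must be non-negative")
  if (any(assay$c1 > assay$c0 + 1e-12))
    stop("post-staining concentration exceeds initial concentration: assay error")
  assay
}

#' Construct a hydroponic pot sample
#'
#' One pot's solution state at one sampling time: total solution volume and
#' the NH4+ and NO3- concentrations, with the pot's plant count. Blank pots
#' (no plants) measure abiotic losses from volatilisation, denitrification
#' and evaporation.
#'
#' @param pot_id Pot identifier.
#' @param day Days after germination at sampling.
#' @param volume_L Total solution volume (L).
#' @param c_nh4_mM,c_no3_mM NH4+ and NO3- concentrations (mmol L^-1).
#' @param n_plants Number of plants in the pot (0 for blanks).
#' @param is_blank Logical; must agree with `n_plants == 0`.
#' @return A one-row data.frame.
#' @export
pot_sample <- function(pot_id, day, volume_L, c_nh4_mM, c_no3_mM,
                       n_plants, is_blank = n_plants == 0) {
  stopifnot(volume_L >= 0, c_nh4_mM >= 0, c_no3_mM >= 0, n_plants >= 0)
  if (is_blank != (n_plants == 0))
    stop("blank pots must have n_plants = 0 and vice versa")
  data.frame(pot_id = pot_id, day = day, volume_L = volume_L,
             c_nh4_mM = c_nh4_mM, c_no3_mM = c_no3_mM,
             n_plants = n_plants, is_blank = is_blank)
}

#' Blank-corrected per-plant uptake rates from a hydroponic pot pair
#'
#' Nutrient-depletion mass balance over one day. With fresh-solution state
#' (V1, c11, c12) and next-day state (V2, c21, c22) of a planted pot, and
#' the corresponding blank-pot states (primed), per-plant daily rates are
#' \deqn{v(NH_4^+) = [V_1 c_{11} - V_2 c_{21} -
#'   (V_1' c_{11}' - V_2' c_{21}')]/N_p}
#' \deqn{v(NO_3^-) = [V_1 c_{12} - V_2 c_{22} -
#'   (V_1' c_{12}' - V_2' c_{22}')]/N_p}
#' \deqn{v(T) = [V_1 - V_2 - (V_1' - V_2')]/N_p,}
#' where the blank terms subtract abiotic nutrient and water losses. The
#' total nitrogen rate is the molar sum `v_nh4 + v_no3` (each ion carries
#' one N atom). Negative rates are returned unclipped and flagged in
#' `suspect`: the blank correction can legitimately overshoot under noise,
#' and clipping would bias group means.
#'
#' @param pot_day0,pot_day1 Treatment-pot samples on consecutive days
#'   (same `pot_id`, `n_plants >= 1`); see [pot_sample()].
#' @param blank_day0,blank_day1 Blank-pot samples on the same days.
#' @return A one-row data.frame with `v_nh4`, `v_no3`, `v_total_n`
#'   (mmol plant^-1 day^-1), `v_t` (L plant^-1 day^-1) and `suspect`.
#' @export
uptake_rates <- function(pot_day0, pot_day1, blank_day0, blank_day1) {
  if (!identical(pot_day0$pot_id, pot_day1$pot_id))
    stop("treatment pots must share pot_id")
  if (!isTRUE(blank_day0$is_blank) || !isTRUE(blank_day1$is_blank))
    stop("blank samples must be blank pots")
  if (pot_day0$is_blank || pot_day0$n_plants < 1)
    stop("treatment pot must contain at least one plant")
  if (pot_day1$day - pot_day0$day != 1 || blank_day1$day - blank_day0$day != 1)
    stop("samples must be taken one day apart")
  np <- pot_day0$n_plants
  blank_nh4 <- blank_day0$volume_L * blank_day0$c_nh4_mM -
    blank_day1$volume_L * blank_day1$c_nh4_mM
  blank_no3 <- blank_day0$volume_L * blank_day0$c_no3_mM -
    blank_day1$volume_L * blank_day1$c_no3_mM
  v_nh4 <- (pot_day0$volume_L * pot_day0$c_nh4_mM -
              pot_day1$volume_L * pot_day1$c_nh4_mM - blank_nh4) / np
  v_no3 <- (pot_day0$volume_L * pot_day0$c_no3_mM -
              pot_day1$volume_L * pot_day1$c_no3_mM - blank_no3) / np
  v_t <- (pot_day0$volume_L - pot_day1$volume_L -
            (blank_day0$volume_L - blank_day1$volume_L)) / np
  data.frame(pot_id = pot_day0$pot_id, day = pot_day0$day,
             v_nh4 = v_nh4, v_no3 = v_no3, v_total_n = v_nh4 + v_no3,
             v_t = v_t, suspect = v_nh4 < 0 | v_no3 < 0 | v_t < 0)
}

#' Normalise an uptake rate by root area or root mass
#'
#' Uptake rates per plant are compared between cultivars on an active
#' uptake-area basis and on a root dry-weight basis.
#'
#' @param rate Per-plant rate (e.g. mmol plant^-1 day^-1).
#' @param denom Positive denominator: active uptake area or root dry
#'   weight (g).
#' @return `rate / denom`.
#' @export
normalize_rate <- function(rate, denom) {
  if (any(denom <= 0)) stop("normalisation denominator must be positive")
  rate / denom
}
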