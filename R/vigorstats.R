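#' Percent difference of a test group over a reference group
#'
#' The convention used throughout the cultivar comparisons: a trait mean of
#' the test cultivar is expressed as its percent excess over the reference
#' cultivar, `100 * (mean_test - mean_ref) / mean_ref`. Ratios of group
#' means, not means of per-plant ratios.
#'
#' @param mean_test,mean_ref Group means; `mean_ref` must be positive.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(1.53, 1.00)  # 53
percent_difference <- function(mean_test, mean_ref) {
  if (any(mean_ref <= 0)) stop("reference mean must be positive")
  100 * (mean_test - mean_ref) / mean_ref
}

#' Two-sided pooled-variance Student's t-test
#'
#' Wrapper around [stats::t.test()] with `var.equal = TRUE` (the classical
#' Student test named in the study design; set `welch = TRUE` for the
#' unequal-variance variant). Significance stars follow the 0.05 / 0.01
#' convention: `"*"` for p < 0.05, `"**"` for p < 0.01.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param welch Logical; use the Welch approximation instead of pooling.
#' @return List with `t`, `p`, `df` and `stars`.
#' @export
students_t_test <- function(sample_a, sample_b, welch = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    # degenerate: zero pooled variance
    if (mean(sample_a) == mean(sample_b)) {
      res <- list(t = 0, p = 1, df = length(sample_a) + length(sample_b) - 2)
    } else {
      res <- list(t = sign(mean(sample_a) - mean(sample_b)) * Inf, p = 0,
                  df = length(sample_a) + length(sample_b) - 2)
    }
  } else {
    ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
    res <- list(t = unname(ht$statistic), p = ht$p.value,
                df = unname(ht$parameter))
  }
  res$stars <- significance_stars(res$p)
  res
}

#' @rdname students_t_test
#' @param p P-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Ordinary least-squares regression with R-squared
#'
#' Pooled simple linear regression (both cultivars in one fit), used for the
#' seed-reserve vs seedling-biomass relationship. Delegates to
#' [stats::lm()].
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return List with `slope`, `intercept`, `r_squared` and `n`.
#' @export
ols_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(x))
}

#' Root to shoot dry-weight ratio
#'
#' @param root_dw,shoot_dw Dry weights (g); `shoot_dw` must be positive.
#' @return `root_dw / shoot_dw`. Vectorised.
#' @export
root_shoot_ratio <- function(root_dw, shoot_dw) {
  if (any(shoot_dw <= 0)) stop("shoot dry weight must be positive")
  root_dw / shoot_dw
}

#' Compare a trait between two cultivars at one timepoint
#'
#' Assembles group means and SDs, the percent difference of the test
#' cultivar over the reference, and a pooled-variance Student's t-test with
#' significance stars.
#'
#' @param records Data frame with columns `cultivar`, `dag`, `trait`,
#'   `value` (long format, one row per plant measurement).
#' @param trait Trait name to compare.
#' @param dag Timepoint (days after germination).
#' @param test Test cultivar (percent difference is test over reference).
#' @param ref Reference cultivar.
#' @return One-row data.frame with means, sds, ns, `percent_diff`,
#'   `t_stat`, `p_value` and `stars`.
#' @export
compare_cultivars <- function(records, trait, dag, test = "9311",
                              ref = "HHZ") {
  stopifnot(all(c("cultivar", "dag", "trait", "value") %in% names(records)))
  sub <- records[records$trait == trait & records$dag == dag, ]
  va <- sub$value[sub$cultivar == test]
  vb <- sub$value[sub$cultivar == ref]
  if (length(va) == 0 || length(vb) == 0)
    stop(sprintf("missing group for trait '%s' at %s DAG", trait, dag))
  tt <- students_t_test(va, vb)
  data.frame(trait = trait, dag = dag, cultivar_test = test,
             cultivar_ref = ref,
             mean_test = mean(va), mean_ref = mean(vb),
             sd_test = stats::sd(va), sd_ref = stats::sd(vb),
             n_test = length(va), n_ref = length(vb),
             percent_diff = percent_difference(mean(va), mean(vb)),
             t_stat = tt$t, p_value = tt$p, stars = tt$stars)
}

#' Summarise root morphology by root class
#'
#' Grouped means and SDs of length, diameter and count per root class at a
#' timepoint. Root classes of the rice root system: the seminal root,
#' shoot-borne crown roots, branching L-type lateral roots, non-branching
#' S-type lateral roots, and second-order laterals. A class/cultivar cell
#' with no records is reported with `observed = FALSE` (figure convention
#' "NO", not observed), e.g. L-type laterals absent on one cultivar early on.
#'
#' @param records Data frame with columns `cultivar`, `dag`, `root_class`,
#'   `length_cm`, `diameter_mm`, `count`.
#' @param dag Timepoint to summarise.
#' @param classes Root classes to report (rows are emitted for every
#'   cultivar x class combination, observed or not).
#' @return Data frame with one row per cultivar x root class.
#' @export
summarize_root_morphology <- function(records, dag,
                                      classes = c("seminal", "crown", "L_LR",
                                                  "S_LR", "secondary_LR")) {
  stopifnot(nrow(records) > 0,
            all(c("cultivar", "dag", "root_class") %in% names(records)))
  sub <- records[records$dag == dag, ]
  cultivars <- sort(unique(records$cultivar))
  grid <- expand.grid(cultivar = cultivars, root_class = classes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- sub[sub$cultivar == grid$cultivar[i] &
               sub$root_class == grid$root_class[i], ]
    if (nrow(g) == 0) {
      data.frame(cultivar = grid$cultivar[i], root_class = grid$root_class[i],
                 dag = dag, observed = FALSE, n = 0L,
                 mean_length_cm = NA_real_, sd_length_cm = NA_real_,
                 mean_diameter_mm = NA_real_, sd_diameter_mm = NA_real_,
                 mean_count = NA_real_, sd_count = NA_real_)
    } else {
      data.frame(cultivar = grid$cultivar[i], root_class = grid$root_class[i],
                 dag = dag, observed = TRUE, n = nrow(g),
                 mean_length_cm = mean(g$length_cm),
                 sd_length_cm = stats::sd(g$length_cm),
                 mean_diameter_mm = mean(g$diameter_mm),
                 sd_diameter_mm = stats::sd(g$diameter_mm),
                 mean_count = mean(g$count),
                 sd_count = stats::sd(g$count))
    }
  })
  do.call(rbind, rows)
}
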