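#' Rubisco kinetic constants at 25 degrees C
#'
#' Default Michaelis constants for carboxylation (`Kc`) and oxygenation
#' (`Ko`), the CO2 compensation point in the absence of day respiration
#' (`Gamma_star`) and the chloroplastic O2 mole fraction (`O`), after the
#' widely used in-vivo tobacco calibration at 25 degrees C. Block temperature
#' in the measurement protocol is held at 26 degrees C and no temperature
#' response is applied.
#'
#' @param Kc Michaelis constant of Rubisco for CO2 (umol mol^-1).
#' @param Ko Michaelis constant of Rubisco for O2 (mmol mol^-1).
#' @param Gamma_star CO2 compensation point without day respiration
#'   (umol mol^-1).
#' @param O O2 mole fraction (mmol mol^-1).
#' @return A named list of class `kinetic_constants`.
#' @export
#' @examples
#' kinetic_constants()
kinetic_constants <- function(Kc = 404.9, Ko = 278.4, Gamma_star = 42.75,
                              O = 210) {
  stopifnot(Kc > 0, Ko > 0, Gamma_star > 0, O > 0)
  structure(list(Kc = Kc, Ko = Ko, Gamma_star = Gamma_star, O = O),
            class = "kinetic_constants")
}

#' Measurement protocol grids
#'
#' The light and CO2 setpoint sequences of the gas-exchange protocol:
#' 13 PPFD levels for A-Q curves, and 6 + 7 CO2 setpoints for A-Ci curves
#' (a descending series from ambient followed, after re-equilibration, by an
#' ascending series).
#'
#' @return Numeric vector of setpoints in measurement order.
#' @export
ppfd_levels <- function() {
  c(2000, 1800, 1500, 1200, 1000, 800, 600, 400, 200, 100, 50, 25, 0)
}

#' @rdname ppfd_levels
#' @export
co2_setpoints <- function() {
  c(400, 350, 250, 150, 100, 50, 500, 600, 700, 900, 1100, 1400, 1800)
}

#' FvCB net assimilation
#'
#' Net CO2 assimilation under the Farquhar-von Caemmerer-Berry model of C3
#' photosynthesis as the minimum of the Rubisco-limited rate
#' \deqn{A_c = V_{cmax} (C_i - \Gamma^*) / (C_i + K_c(1 + O/K_o)) - R_d}
#' and the RuBP-regeneration-limited rate
#' \deqn{A_j = J (C_i - \Gamma^*) / (4 C_i + 8 \Gamma^*) - R_d,}
#' with electron transport at its maximum (`J = Jmax`; the A-Ci protocol
#' holds light saturating at 1800 umol photons m^-2 s^-1). Triose-phosphate
#' limitation is not modelled.
#'
#' @param Ci Intercellular CO2 mole fraction (umol mol^-1), vectorised.
#' @param Vcmax Maximum Rubisco carboxylation rate (umol m^-2 s^-1).
#' @param Jmax Maximum electron transport rate (umol m^-2 s^-1).
#' @param Rd Day respiration (umol m^-2 s^-1).
#' @param constants A [kinetic_constants()] list.
#' @return For `fvcb_assimilation`, net assimilation A (umol CO2 m^-2 s^-1);
#'   `fvcb_limits` returns a data.frame with columns `Ac`, `Aj`, `A` and the
#'   binding `limitation` ("Rubisco" or "RuBP").
#' @export
#' @examples
#' fvcb_assimilation(300, Vcmax = 80, Jmax = 500, Rd = 1)
fvcb_assimilation <- function(Ci, Vcmax, Jmax, Rd,
                              constants = kinetic_constants()) {
  fvcb_limits(Ci, Vcmax, Jmax, Rd, constants)$A
}

#' @rdname fvcb_assimilation
#' @export
fvcb_limits <- function(Ci, Vcmax, Jmax, Rd, constants = kinetic_constants()) {
  stopifnot(all(Ci >= 0), Vcmax > 0, Jmax > 0, Rd >= 0)
  Ac <- Vcmax * .fc(Ci, constants) - Rd
  Aj <- Jmax * .fj(Ci, constants) - Rd
  A <- pmin(Ac, Aj)
  data.frame(Ci = Ci, Ac = Ac, Aj = Aj, A = A,
             limitation = ifelse(Ac <= Aj, "Rubisco", "RuBP"))
}

# Carboxylation-efficiency factors: Ac = Vcmax * .fc - Rd, Aj = Jmax * .fj - Rd
.fc <- function(Ci, k) (Ci - k$Gamma_star) / (Ci + k$Kc * (1 + k$O / k$Ko))
.fj <- function(Ci, k) (Ci - k$Gamma_star) / (4 * Ci + 8 * k$Gamma_star)

#' Non-rectangular hyperbola net assimilation
#'
#' Light response of net assimilation,
#' \deqn{A(Q) = \frac{\phi Q + A_{max} -
#'   \sqrt{(\phi Q + A_{max})^2 - 4\theta\phi Q A_{max}}}{2\theta} - R_d,}
#' with the rectangular-hyperbola limit
#' \eqn{\phi Q A_{max} / (\phi Q + A_{max}) - R_d} used for
#' `theta < 1e-6` (the expression is continuous there).
#'
#' @param Q Photosynthetic photon flux density (umol photons m^-2 s^-1),
#'   vectorised.
#' @param phi Apparent quantum yield (mol CO2 mol^-1 photons), in (0, 0.125].
#' @param Amax Gross light-saturated asymptote (umol m^-2 s^-1).
#' @param theta Convexity, in (0, 1]; values below 1e-6 use the limit form.
#' @param Rd Day respiration (umol m^-2 s^-1).
#' @return Net assimilation (umol CO2 m^-2 s^-1).
#' @export
#' @examples
#' nrh_assimilation(500, phi = 0.05, Amax = 25, theta = 0.7, Rd = 1)
nrh_assimilation <- function(Q, phi, Amax, theta, Rd) {
  stopifnot(all(Q >= 0), phi > 0, phi <= 0.125, Amax > 0,
            theta >= 0, theta <= 1, Rd >= 0)
  s <- phi * Q + Amax
  if (theta < 1e-6) {
    gross <- ifelse(s > 0, phi * Q * Amax / s, 0)
  } else {
    disc <- pmax(s^2 - 4 * theta * phi * Q * Amax, 0)
    gross <- (s - sqrt(disc)) / (2 * theta)
  }
  gross - Rd
}

#' Fit the FvCB model to an A-Ci curve by limitation-state segmentation
#'
#' Points are sorted by Ci; because both limitation rates increase with Ci
#' and the Rubisco-limited rate binds at low Ci, every admissible assignment
#' of points to limitation states is a contiguous split with all
#' Rubisco-limited points below all RuBP-limited points. All `n + 1` such
#' segmentations (all-Rubisco, all-RuBP, and each breakpoint) are enumerated;
#' under a fixed assignment the model is linear in `(Vcmax, Jmax, Rd)`, so
#' each candidate is solved exactly by linear least squares. A candidate is
#' admissible when the parameters satisfy `Vcmax > 0`, `Jmax > 0`, `Rd >= 0`
#' and, at every point, the assigned state's modelled rate does not exceed
#' the other state's rate by more than `tol_limitation`. The admissible
#' candidate with minimal SSE is returned (ties broken toward fewer
#' RuBP-limited points); if none is admissible the overall minimal-SSE
#' candidate is returned with `admissible = FALSE`.
#'
#' @param curve Data frame with numeric columns `driver_value` (Ci,
#'   umol mol^-1) and `A` (umol m^-2 s^-1); a `driver_kind` column, if
#'   present, must equal "Ci". At least 5 points with distinct Ci.
#' @param constants A [kinetic_constants()] list.
#' @param tol_limitation Admissibility tolerance for limitation consistency
#'   (umol m^-2 s^-1).
#' @return An object of class `fvcb_fit`: list with `Vcmax`, `Jmax`, `Rd`
#'   (NA for a state absent from the selected segmentation), `sse`,
#'   `assignment` (per-point state in Ci order), `admissible`,
#'   `n_candidates`, and `fitted`/`residuals` in Ci order.
#' @seealso [fit_aq()] for A-Q light-response curves.
#' @export
fit_aci <- function(curve, constants = kinetic_constants(),
                    tol_limitation = 0.5) {
  curve <- .check_curve(curve, "Ci", min_points = 5L)
  ci <- curve$driver_value
  a <- curve$A
  ord <- order(ci)
  ci <- ci[ord]
  a <- a[ord]
  n <- length(ci)
  fc <- .fc(ci, constants)
  fj <- .fj(ci, constants)

  candidates <- .aci_segmentations(n)
  fits <- lapply(candidates, function(st) .fit_aci_segment(st, ci, a, fc, fj,
                                                           constants,
                                                           tol_limitation))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("least-squares solve failed for every segmentation")
  fits <- fits[ok]
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  adm <- vapply(fits, `[[`, logical(1), "admissible")
  n_rubp <- vapply(fits, function(f) sum(f$assignment == "RuBP"), numeric(1))
  pool <- if (any(adm)) which(adm) else seq_along(fits)
  # minimal SSE; among (numerically) tied SSEs prefer fewer RuBP points
  best_sse <- min(sse[pool])
  tied <- pool[sse[pool] <= best_sse + 1e-12 * max(1, best_sse)]
  best <- tied[which.min(n_rubp[tied])]
  out <- fits[[best]]
  out$n_candidates <- length(candidates)
  out$curve <- data.frame(Ci = ci, A = a)
  class(out) <- "fvcb_fit"
  out
}

# All contiguous limitation assignments for n Ci-sorted points:
# all-Rubisco, all-RuBP, and breakpoints k = 1..n-1 (first k points Rubisco).
.aci_segmentations <- function(n) {
  ks <- c(n, 0, seq_len(n - 1))
  lapply(ks, function(k) rep(c("Rubisco", "RuBP"), c(k, n - k)))
}

.fit_aci_segment <- function(state, ci, a, fc, fj, constants, tol) {
  is_c <- state == "Rubisco"
  X <- cbind(Vcmax = fc * is_c, Jmax = fj * !is_c, Rd = -1)
  use <- c(any(is_c), any(!is_c), TRUE)
  beta <- tryCatch(qr.coef(qr(X[, use, drop = FALSE]), a),
                   error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) return(NULL)
  par <- c(Vcmax = NA_real_, Jmax = NA_real_, Rd = NA_real_)
  par[colnames(X)[use]] <- beta
  fitted <- as.numeric(X[, use, drop = FALSE] %*% beta)
  sse <- sum((a - fitted)^2)

  pos_ok <- (is.na(par["Vcmax"]) || par["Vcmax"] > 0) &&
    (is.na(par["Jmax"]) || par["Jmax"] > 0) && par["Rd"] >= -1e-9
  lim_ok <- TRUE
  if (pos_ok) {
    ac <- if (is.na(par["Vcmax"])) rep(Inf, length(ci)) else
      par["Vcmax"] * fc - par["Rd"]
    aj <- if (is.na(par["Jmax"])) rep(Inf, length(ci)) else
      par["Jmax"] * fj - par["Rd"]
    assigned <- ifelse(is_c, ac, aj)
    other <- ifelse(is_c, aj, ac)
    lim_ok <- all(assigned <= other + tol)
  }
  list(Vcmax = unname(par["Vcmax"]), Jmax = unname(par["Jmax"]),
       Rd = unname(max(par["Rd"], 0)), sse = sse, assignment = state,
       admissible = pos_ok && lim_ok, fitted = fitted,
       residuals = a - fitted)
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB A-Ci fit\n")
  cat(sprintf("  Vcmax = %.3f  Jmax = %.3f  Rd = %.3f  (umol m-2 s-1)\n",
              x$Vcmax, x$Jmax, x$Rd))
  cat(sprintf("  SSE = %.4g over %d points; %d Rubisco / %d RuBP; %s\n",
              x$sse, length(x$assignment), sum(x$assignment == "Rubisco"),
              sum(x$assignment == "RuBP"),
              if (x$admissible) "admissible" else "NOT admissible"))
  invisible(x)
}

#' Fit the non-rectangular hyperbola to an A-Q light-response curve
#'
#' Bounded nonlinear least squares of `(phi, Amax, theta, Rd)` via
#' Levenberg-Marquardt, from a small multistart grid
#' (`phi` in {0.03, 0.05, 0.08} x `theta` in {0.3, 0.7, 0.95}, with
#' `Rd0 = max(0, -A at the lowest Q)` and `Amax0 = max(A) + Rd0`). The
#' light-saturated net rate is reported as the plateau `Asat = Amax - Rd`.
#'
#' @param curve Data frame with numeric columns `driver_value` (PPFD,
#'   umol photons m^-2 s^-1) and `A`; a `driver_kind` column, if present,
#'   must equal "PPFD". At least 5 points, at least one with Q < 100 so the
#'   initial slope is constrained.
#' @return An object of class `nrh_fit`: list with `phi`, `Amax`, `theta`,
#'   `Rd`, `Asat`, `sse`, `fitted`, `residuals` (in Q order) and `curve`.
#' @seealso [fit_aci()]
#' @export
fit_aq <- function(curve) {
  curve <- .check_curve(curve, "PPFD", min_points = 5L)
  ord <- order(curve$driver_value)
  q <- curve$driver_value[ord]
  a <- curve$A[ord]
  if (min(q) >= 100)
    stop("A-Q fitting needs at least one point with Q < 100 to constrain phi")
  if (diff(range(a)) == 0) stop("degenerate curve: all A values are equal")

  rd0 <- max(0, -a[1])
  amax0 <- max(a) + rd0
  lower <- c(phi = 1e-4, Amax = 1e-3, theta = 1e-8, Rd = 0)
  upper <- c(phi = 0.125, Amax = Inf, theta = 1, Rd = Inf)
  resid_fun <- function(p) {
    a - nrh_assimilation(q, p[["phi"]], p[["Amax"]], p[["theta"]], p[["Rd"]])
  }
  best <- NULL
  for (phi0 in c(0.03, 0.05, 0.08)) {
    for (theta0 in c(0.3, 0.7, 0.95)) {
      start <- c(phi = phi0, Amax = amax0, theta = theta0, Rd = max(rd0, 0.01))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = fit$par, sse = sse)
    }
  }
  if (is.null(best)) stop("NRH fit failed to converge from every start")
  p <- best$par
  fitted <- nrh_assimilation(q, p[["phi"]], p[["Amax"]], p[["theta"]],
                             p[["Rd"]])
  structure(list(phi = p[["phi"]], Amax = p[["Amax"]], theta = p[["theta"]],
                 Rd = p[["Rd"]], Asat = p[["Amax"]] - p[["Rd"]],
                 sse = best$sse, fitted = fitted, residuals = a - fitted,
                 curve = data.frame(Q = q, A = a)),
            class = "nrh_fit")
}

#' @export
print.nrh_fit <- function(x, ...) {
  cat("Non-rectangular hyperbola A-Q fit\n")
  cat(sprintf("  phi = %.4f  Amax = %.3f  theta = %.3f  Rd = %.3f\n",
              x$phi, x$Amax, x$theta, x$Rd))
  cat(sprintf("  Asat = %.3f umol m-2 s-1; SSE = %.4g over %d points\n",
              x$Asat, x$sse, nrow(x$curve)))
  invisible(x)
}

.check_curve <- function(curve, kind, min_points) {
  stopifnot(is.data.frame(curve),
            all(c("driver_value", "A") %in% names(curve)))
  if ("driver_kind" %in% names(curve)) {
    kinds <- unique(curve$driver_kind)
    if (!identical(kinds, kind))
      stop(sprintf("curve driver_kind is '%s', expected '%s'",
                   paste(kinds, collapse = ","), kind))
  }
  if (nrow(curve) < min_points)
    stop(sprintf("curve has %d points; at least %d required",
                 nrow(curve), min_points))
  if (anyDuplicated(curve$driver_value))
    stop("driver values must be distinct")
  if (any(curve$driver_value < 0) || any(!is.finite(curve$A)))
    stop("driver values must be non-negative and A finite")
  curve
}
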