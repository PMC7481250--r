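#' Leaf nitrogen content of a 10-cm leaf segment
#'
#' A 10-cm segment of the leaf used for gas exchange is dried and analysed;
#' area-based leaf nitrogen content is
#' \deqn{LNC = c_N \, m_L / (10\, w_L) \times 10000 \quad (g\,m^{-2}),}
#' with `c_N` the nitrogen mass fraction (g g^-1), `m_L` the segment dry
#' mass (g) and `w_L` the leaf width (cm); `10 * w_L` cm^2 is the segment's
#' projected area and the factor 10000 converts cm^2 to m^2. If your
#' elemental-analyser output is in percent, set `percent = TRUE`.
#'
#' @param n_fraction Nitrogen mass fraction `c_N` (g g^-1), or percent if
#'   `percent = TRUE`. Must lie in [0, 0.15) as a fraction.
#' @param dry_mass_g Segment dry mass `m_L` (g), positive.
#' @param width_cm Leaf width `w_L` (cm), positive.
#' @param percent Logical; interpret `n_fraction` as percent and divide
#'   by 100.
#' @return LNC in g m^-2. Vectorised over all arguments.
#' @export
#' @examples
#' leaf_nitrogen_content(0.02, dry_mass_g = 0.05, width_cm = 1)  # 1 g m^-2
leaf_nitrogen_content <- function(n_fraction, dry_mass_g, width_cm,
                                  percent = FALSE) {
  if (percent) n_fraction <- n_fraction / 100
  stopifnot(all(n_fraction >= 0), all(n_fraction < 0.15))
  .check_segment(dry_mass_g, width_cm)
  n_fraction * dry_mass_g / (10 * width_cm) * 10000
}

#' Specific leaf weight of a 10-cm leaf segment
#'
#' Dry mass per unit projected leaf area, `SLW = m_L / (10 w_L 10^{-4})`
#' in g m^-2. By construction `LNC = SLW * c_N` for any segment.
#'
#' @inheritParams leaf_nitrogen_content
#' @return SLW in g m^-2. Vectorised.
#' @export
#' @examples
#' specific_leaf_weight(0.05, width_cm = 1)  # 50 g m^-2
specific_leaf_weight <- function(dry_mass_g, width_cm) {
  .check_segment(dry_mass_g, width_cm)
  dry_mass_g / (10 * width_cm * 1e-4)
}

.check_segment <- function(dry_mass_g, width_cm) {
  if (any(dry_mass_g <= 0)) stop("segment dry mass must be positive")
  if (any(width_cm <= 0)) stop("leaf width must be positive")
  invisible(NULL)
}
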