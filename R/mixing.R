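#' Two-endmember Sr isotope mixing model parameters
#'
#' Conservative mixing of river water with seawater sets both the strontium
#' concentration and the 87Sr/86Sr ratio of estuarine water. Because seawater
#' carries far more Sr (~7.9 mg/L at 35 PSU) than river water (~0.25 mg/L),
#' the mixing curve is very steep at low salinity, which is what gives otolith
#' 87Sr/86Sr its resolution across the freshwater-to-brackish transition.
#'
#' The freshwater endmember ratio `R_fresh` is normally not set directly but
#' calibrated so that the curve passes through an anchor point - by default
#' the 0.5 PSU freshwater/brackish boundary at a ratio of 0.7075
#' (see [calibrate_freshwater_endmember()]).
#'
#' @param R_ocean seawater 87Sr/86Sr (globally uniform, default 0.70918)
#' @param Sr_ocean seawater Sr concentration, mg/L
#' @param S_ocean seawater salinity, PSU
#' @param Sr_fresh freshwater Sr concentration, mg/L
#' @param R_fresh freshwater 87Sr/86Sr; `NA` until calibrated
#' @param anchor_ratio,anchor_salinity anchor point the calibrated curve must
#'   pass through (ratio, PSU)
#' @return an object of class `"sr_mixing"`
#' @seealso [ratio_from_salinity()], [salinity_from_ratio()]
#' @export
mixing_params <- function(R_ocean = 0.70918, Sr_ocean = 7.9, S_ocean = 35,
                          Sr_fresh = 0.25, R_fresh = NA_real_,
                          anchor_ratio = 0.7075, anchor_salinity = 0.5) {
  stopifnot(Sr_ocean > Sr_fresh, Sr_fresh > 0,
            anchor_salinity > 0, anchor_salinity < S_ocean)
  p <- list(R_ocean = R_ocean, Sr_ocean = Sr_ocean, S_ocean = S_ocean,
            Sr_fresh = Sr_fresh, R_fresh = R_fresh,
            anchor_ratio = anchor_ratio, anchor_salinity = anchor_salinity)
  class(p) <- "sr_mixing"
  p
}

#' @export
print.sr_mixing <- function(x, ...) {
  cat("Two-endmember Sr mixing model\n")
  cat(sprintf("  ocean: R = %.5f, Sr = %.2f mg/L, S = %g PSU\n",
              x$R_ocean, x$Sr_ocean, x$S_ocean))
  cat(sprintf("  fresh: R = %s, Sr = %.3f mg/L\n",
              if (is.na(x$R_fresh)) "<uncalibrated>" else
                sprintf("%.5f", x$R_fresh), x$Sr_fresh))
  cat(sprintf("  anchor: %.4f at %g PSU\n", x$anchor_ratio, x$anchor_salinity))
  invisible(x)
}

#' Calibrate the freshwater endmember ratio
#'
#' Solves `R_fresh` in closed form so the mixing curve passes exactly through
#' the anchor point (by default a ratio of 0.7075 at the 0.5 PSU
#' freshwater/brackish boundary). With seawater fraction
#' `f = S_a / S_ocean` and `Sr_mix = f*Sr_ocean + (1-f)*Sr_fresh`, the anchor
#' condition is linear in `R_fresh`:
#' `R_fresh = (R_a * Sr_mix - f * Sr_ocean * R_ocean) / ((1-f) * Sr_fresh)`.
#'
#' @param params an `sr_mixing` object
#' @return the same object with `R_fresh` filled in
#' @export
calibrate_freshwater_endmember <- function(params = mixing_params()) {
  stopifnot(inherits(params, "sr_mixing"))
  f <- params$anchor_salinity / params$S_ocean
  sr_mix <- f * params$Sr_ocean + (1 - f) * params$Sr_fresh
  r_fresh <- (params$anchor_ratio * sr_mix -
                f * params$Sr_ocean * params$R_ocean) /
    ((1 - f) * params$Sr_fresh)
  if (!is.finite(r_fresh) || r_fresh >= params$anchor_ratio)
    stop("mixing calibration infeasible: solved R_fresh (", format(r_fresh),
         ") is not below the anchor ratio", call. = FALSE)
  params$R_fresh <- r_fresh
  params
}

check_calibrated <- function(params) {
  if (!inherits(params, "sr_mixing") || is.na(params$R_fresh))
    stop("mixing params must be calibrated first; see calibrate_freshwater_endmember()",
         call. = FALSE)
  invisible(params)
}

#' Forward mixing model: salinity to 87Sr/86Sr
#'
#' Salinity is mapped to a seawater mass fraction `f = S / S_ocean` (river
#' salinity taken as zero), and the water ratio is the Sr-weighted mean of the
#' two endmember ratios:
#' `R = (f*Sr_ocean*R_ocean + (1-f)*Sr_fresh*R_fresh) / (f*Sr_ocean + (1-f)*Sr_fresh)`.
#'
#' @param S salinity, PSU; vectorized. Must lie in `[0, S_ocean]`.
#' @param params calibrated `sr_mixing` parameters
#' @return 87Sr/86Sr ratio(s)
#' @export
ratio_from_salinity <- function(S, params = calibrate_freshwater_endmember()) {
  check_calibrated(params)
  if (any(S < 0 | S > params$S_ocean))
    stop("salinity outside [0, ", params$S_ocean, "] PSU", call. = FALSE)
  f <- S / params$S_ocean
  w_sea <- f * params$Sr_ocean
  w_fresh <- (1 - f) * params$Sr_fresh
  (w_sea * params$R_ocean + w_fresh * params$R_fresh) / (w_sea + w_fresh)
}

#' Inverse mixing model: 87Sr/86Sr to salinity
#'
#' Exact algebraic inversion of [ratio_from_salinity()]: cross-multiplying the
#' forward formula gives a linear equation in the seawater fraction `f`,
#' `f = Sr_fresh*(R - R_fresh) / (Sr_ocean*(R_ocean - R) + Sr_fresh*(R - R_fresh))`,
#' and salinity is `f * S_ocean`. Ratios outside `[R_fresh, R_ocean]` by no
#' more than `tol` (measurement noise around the freshwater endmember) are
#' clamped to the boundary with a warning; larger excursions are an error.
#'
#' @param R 87Sr/86Sr ratio(s)
#' @param params calibrated `sr_mixing` parameters
#' @param tol clamping tolerance on the ratio scale (default 5e-5, about
#'   twice a typical per-day ratio noise)
#' @return salinity, PSU
#' @export
salinity_from_ratio <- function(R, params = calibrate_freshwater_endmember(),
                                tol = 5e-5) {
  check_calibrated(params)
  lo <- params$R_fresh
  hi <- params$R_ocean
  if (any(R < lo - tol | R > hi + tol))
    stop("ratio outside mixing-model range [",
         format(lo), ", ", format(hi), "] by more than ", format(tol),
         call. = FALSE)
  out_of_range <- R < lo | R > hi
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " ratio(s) outside the endmember range clamped to the boundary")
    R <- pmin(pmax(R, lo), hi)
  }
  f <- params$Sr_fresh * (R - lo) /
    (params$Sr_ocean * (hi - R) + params$Sr_fresh * (R - lo))
  f * params$S_ocean
}

#' Fill the salinity track of a chronology
#'
#' Applies the inverse mixing model pointwise to the daily ratio series.
#'
#' @param chron an `sr_chronology` (see [align_profile()])
#' @param params calibrated `sr_mixing` parameters
#' @param tol clamping tolerance passed to [salinity_from_ratio()]
#' @return the chronology with its `salinity` column filled
#' @export
chronology_to_salinity <- function(chron, params = calibrate_freshwater_endmember(),
                                   tol = 5e-5) {
  stopifnot(inherits(chron, "sr_chronology"))
  chron$salinity <- salinity_from_ratio(chron$ratio, params, tol = tol)
  chron
}
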