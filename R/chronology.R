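# Merge distance-resolved isotope profiles with daily increment widths into
# daily-age chronologies via proportional-distance regression splines.

#' Proportional-distance age map from daily increments
#'
#' Cumulative daily increment widths give the otolith radius at each age;
#' dividing by the radius at capture converts absolute to proportional
#' distance, so the profile (normalized the same way) can be predicted onto
#' the age transect.
#'
#' @param increments numeric vector of daily increment widths (µm), day 1 to
#'   age at capture
#' @return list with `ages` (0..T) and `p` (proportional radius, 0 at the
#'   core, 1 at the edge, strictly increasing)
#' @export
build_age_map <- function(increments) {
  increments <- as.numeric(increments)
  if (length(increments) < 1 || any(increments <= 0))
    stop("increment widths must all be positive", call. = FALSE)
  r <- cumsum(increments)
  list(ages = 0:length(increments), p = c(0, r / r[length(r)]))
}

#' Predict an isotope profile onto the daily age transect
#'
#' Profile distances are normalized to proportional distance by the edge
#' (maximum) distance and a cubic B-spline regression basis with `df` degrees
#' of freedom (interior knots at equally spaced quantiles of the observed
#' proportional distances) is least-squares fitted to ratio versus
#' proportional distance. The fit is evaluated at each age's proportional
#' radius; ages mapping outside the observed distance range take the fit at
#' the nearest observed endpoint rather than extrapolating the basis.
#'
#' @param profile an [isotope_profile()]
#' @param age_map output of [build_age_map()]
#' @param df spline degrees of freedom (default 10)
#' @param method `"regression"` for the B-spline regression fit (default,
#'   deterministic) or `"smoothing"` for `stats::smooth.spline` at the same
#'   equivalent df
#' @return an `"sr_chronology"`: data frame `age`, `ratio`, `salinity` (NA
#'   until [chronology_to_salinity()]) with the fish id as attribute
#' @export
align_profile <- function(profile, age_map, df = 10,
                          method = c("regression", "smoothing")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "isotope_profile"))
  if (nrow(profile) < df + 4)
    stop("too few profile points (", nrow(profile), ") for a df=", df,
         " spline fit", call. = FALSE)
  p_obs <- profile$distance_um / max(profile$distance_um)
  p_new <- pmin(pmax(age_map$p, min(p_obs)), max(p_obs))
  if (method == "regression") {
    basis <- splines::bs(p_obs, df = df)
    fit <- stats::lm.fit(cbind(1, basis), profile$ratio)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0  # rank-deficient basis columns contribute nothing
    newb <- cbind(1, predict(basis, p_new))
    ratio <- drop(newb %*% coefs)
  } else {
    fit <- stats::smooth.spline(p_obs, profile$ratio, df = df)
    ratio <- stats::predict(fit, p_new)$y
  }
  sr_chronology(data.frame(age = age_map$ages, ratio = ratio,
                           salinity = NA_real_),
                fish_id = profile$fish_id[1])
}

#' Construct / validate a daily chronology
#'
#' @param df data frame with `age` (consecutive integer days from 0),
#'   `ratio`, and optionally `salinity`
#' @param fish_id fish identifier
#' @return object of class `"sr_chronology"`
#' @export
sr_chronology <- function(df, fish_id = "fish") {
  stopifnot(all(c("age", "ratio") %in% names(df)))
  if (!all(diff(df$age) == 1) || df$age[1] != 0)
    stop("chronology ages must run 0,1,2,... without gaps", call. = FALSE)
  if (is.null(df$salinity)) df$salinity <- NA_real_
  structure(as.data.frame(df), class = c("sr_chronology", "data.frame"),
            fish_id = fish_id)
}

#' @export
print.sr_chronology <- function(x, ...) {
  cat(sprintf("Chronology %s: ages 0-%d, ratio %.5f-%.5f%s\n",
              attr(x, "fish_id"), max(x$age), min(x$ratio), max(x$ratio),
              if (all(is.na(x$salinity))) "" else
                sprintf(", salinity %.2f-%.2f PSU",
                        min(x$salinity), max(x$salinity))))
  invisible(x)
}

#' Trim a chronology to a common length for clustering
#'
#' Time-series clustering needs equal-length series, so chronologies are cut
#' to the first `max_age` days of life. Shorter fish cannot be trimmed and
#' are excluded (error of class `otolithsr_exclusion`, caught and logged at
#' cohort level).
#'
#' @param chron an `sr_chronology`
#' @param max_age days retained (ages `0 .. max_age - 1`; default 170)
#' @return the trimmed chronology, length exactly `max_age`
#' @export
trim_chronology <- function(chron, max_age = 170) {
  stopifnot(inherits(chron, "sr_chronology"))
  if (max(chron$age) < max_age)
    stop(structure(class = c("otolithsr_exclusion", "error", "condition"),
                   list(message = sprintf(
                     "fish %s: chronology length %d < trim length %d",
                     attr(chron, "fish_id"), max(chron$age) + 1, max_age),
                     call = NULL)))
  out <- chron[chron$age < max_age, , drop = FALSE]
  sr_chronology(out, fish_id = attr(chron, "fish_id"))
}
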