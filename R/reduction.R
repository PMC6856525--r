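# Reduction of raw per-cycle ion intensities to a distance-resolved
# 87Sr/86Sr profile: blank subtraction, Rb interference correction,
# exponential-law mass-bias normalization, moving-window 2-sigma outlier
# rejection.

#' Construct / validate a raw ablation run
#'
#' @param cycles data frame with columns `fish_id`, `time_s`, `i84`, `i85`,
#'   `i86`, `i87`, `i88`, `segment` (one of `blank`, `precore`, `ablation`)
#' @param scan_speed laser traverse speed, µm/s
#' @param spot_diameter_um laser spot diameter, µm
#' @param core_offset_um distance from ablation start to core crossing, µm
#' @return an object of class `"ablation_run"`
#' @export
ablation_run <- function(cycles, scan_speed = 10, spot_diameter_um = 40,
                         core_offset_um = 100) {
  need <- c("fish_id", "time_s", "i84", "i85", "i86", "i87", "i88", "segment")
  miss <- setdiff(need, names(cycles))
  if (length(miss))
    stop("ablation run missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(cycles$time_s, strictly = TRUE))
    stop("cycle times must be strictly increasing", call. = FALSE)
  ints <- as.matrix(cycles[c("i84", "i85", "i86", "i87", "i88")])
  if (any(ints < 0)) stop("negative raw intensities", call. = FALSE)
  if (sum(cycles$segment == "blank") < 10)
    stop("need at least 10 blank cycles", call. = FALSE)
  if (sum(cycles$segment == "ablation") < 50)
    stop("need at least 50 ablation cycles", call. = FALSE)
  structure(as.data.frame(cycles), class = c("ablation_run", "data.frame"),
            scan_speed = scan_speed, spot_diameter_um = spot_diameter_um,
            core_offset_um = core_offset_um,
            blank_subtracted = FALSE, rb_corrected = FALSE)
}

#' @export
print.ablation_run <- function(x, ...) {
  cat(sprintf("Ablation run %s: %d cycles (%d blank / %d precore / %d ablation), %g µm/s\n",
              x$fish_id[1], nrow(x), sum(x$segment == "blank"),
              sum(x$segment == "precore"), sum(x$segment == "ablation"),
              attr(x, "scan_speed")))
  invisible(x)
}

mass_cols <- c("i84", "i85", "i86", "i87", "i88")

#' Blank subtraction
#'
#' Subtracts the per-mass mean of the gas-blank cycles from all non-blank
#' cycles. Negative results are clipped to zero and counted in the
#' `n_clipped` attribute.
#'
#' @param run an [ablation_run()]
#' @return the run with blanks removed; blank means kept in attribute
#'   `blank_means`
#' @export
subtract_blank <- function(run) {
  stopifnot(inherits(run, "ablation_run"))
  if (isTRUE(attr(run, "blank_subtracted")))
    stop("run is already blank-subtracted; reduction steps are single-shot",
         call. = FALSE)
  is_blank <- run$segment == "blank"
  if (!any(is_blank)) stop("no blank segment in run", call. = FALSE)
  bmeans <- colMeans(run[is_blank, mass_cols, drop = FALSE])
  n_clipped <- 0L
  for (m in mass_cols) {
    v <- run[[m]]
    v[!is_blank] <- v[!is_blank] - bmeans[[m]]
    n_clipped <- n_clipped + sum(v < 0)
    run[[m]] <- pmax(v, 0)
  }
  attr(run, "blank_subtracted") <- TRUE
  attr(run, "blank_means") <- bmeans
  attr(run, "n_clipped") <- n_clipped
  run
}

# per-cycle exponential-law mass-bias exponent from the canonical 86/88 ratio
beta_from_86_88 <- function(i86, i88) {
  beta <- rep(NA_real_, length(i86))
  ok <- i86 > 0 & i88 > 0
  beta[ok] <- log(SR86_88_CANONICAL / (i86[ok] / i88[ok])) /
    log(sr_masses[["m86"]] / sr_masses[["m88"]])
  beta
}

#' Rb interference correction on mass 87
#'
#' 87Rb is estimated from the interference-free mass-85 channel through the
#' natural 87Rb/85Rb abundance ratio (0.385710), carried to the measured
#' mass-87 scale with the same exponential mass-bias law used for Sr (the
#' Sr-derived per-cycle exponent), and subtracted from mass 87.
#'
#' @param run a blank-subtracted [ablation_run()]
#' @param max_negative_frac error if the corrected mass-87 goes negative on
#'   more than this fraction of ablation cycles (Rb-dominated signal)
#' @return the run with `i87` interference-corrected
#' @export
correct_rb <- function(run, max_negative_frac = 0.05) {
  stopifnot(inherits(run, "ablation_run"))
  if (!isTRUE(attr(run, "blank_subtracted")))
    stop("blank subtraction must precede the Rb correction", call. = FALSE)
  if (isTRUE(attr(run, "rb_corrected")))
    stop("run is already Rb-corrected", call. = FALSE)
  beta <- beta_from_86_88(run$i86, run$i88)
  adj <- (sr_masses[["m85"]] / sr_masses[["m87"]])^beta
  adj[is.na(adj)] <- 1
  rb87 <- run$i85 * RB87_85_NATURAL * adj
  i87 <- run$i87 - rb87
  abl <- run$segment == "ablation"
  neg_frac <- if (any(abl)) mean(i87[abl] < 0) else 0
  if (neg_frac > max_negative_frac)
    stop(sprintf("Rb-dominated signal: corrected mass-87 negative on %.1f%% of ablation cycles",
                 100 * neg_frac), call. = FALSE)
  run$i87 <- pmax(i87, 0)
  attr(run, "rb_corrected") <- TRUE
  run
}

#' Exponential-law mass-bias normalization
#'
#' Per cycle, the bias exponent is solved from the canonical 86Sr/88Sr
#' (0.1194): `beta = ln(0.1194 / (i86/i88)) / ln(m86/m88)`, and the corrected
#' ratio is `(i87/i86) * (m87/m86)^beta`. Cycles with non-positive i86 or i88
#' are dropped and counted.
#'
#' @param run a blank-subtracted, Rb-corrected [ablation_run()]
#' @return data frame of ablation cycles with `time_s`, `distance_um`
#'   (signed, measured from the core crossing) and `ratio`; dropped-cycle
#'   count in attribute `n_dropped`, scan metadata carried over
#' @export
normalize_mass_bias <- function(run) {
  stopifnot(inherits(run, "ablation_run"))
  if (!isTRUE(attr(run, "blank_subtracted")) || !isTRUE(attr(run, "rb_corrected")))
    stop("mass-bias normalization requires blank-subtracted, Rb-corrected data",
         call. = FALSE)
  abl <- run[run$segment != "blank", , drop = FALSE]
  usable <- abl$i86 > 0 & abl$i88 > 0
  n_dropped <- sum(!usable & abl$segment == "ablation")
  abl <- abl[usable, , drop = FALSE]
  beta <- beta_from_86_88(abl$i86, abl$i88)
  ratio <- (abl$i87 / abl$i86) *
    (sr_masses[["m87"]] / sr_masses[["m86"]])^beta
  blank_end <- max(run$time_s[run$segment == "blank"])
  core_cross <- blank_end + attr(run, "core_offset_um") / attr(run, "scan_speed")
  structure(data.frame(fish_id = abl$fish_id, time_s = abl$time_s,
                       distance_um = (abl$time_s - core_cross) * attr(run, "scan_speed"),
                       ratio = ratio, stringsAsFactors = FALSE),
            n_dropped = n_dropped, mean_beta = mean(beta),
            class = c("sr_ratio_series", "data.frame"))
}

#' Moving-window 2-sigma outlier rejection
#'
#' A single pass flags every point lying more than `k` sample SDs from the
#' mean of its centred `window`-point neighbourhood (windows truncated at the
#' series edges; the point itself is included in its window). Surviving
#' points with non-negative distance from the core form the isotope profile;
#' pre-core points are discarded.
#'
#' @param series output of [normalize_mass_bias()], or a bare numeric ratio
#'   vector (then distances default to the index)
#' @param window moving-window size, points
#' @param k rejection multiplier on the windowed SD
#' @param max_reject_frac quality error if more than this fraction of points
#'   is rejected
#' @return an `"isotope_profile"`: data frame `fish_id`, `distance_um`,
#'   `ratio`, `se`, with attribute `n_rejected`
#' @export
reject_outliers <- function(series, window = 40, k = 2,
                            max_reject_frac = 0.3) {
  if (is.numeric(series))
    series <- structure(data.frame(fish_id = "series",
                                   time_s = seq_along(series),
                                   distance_um = seq_along(series),
                                   ratio = as.numeric(series)),
                        n_dropped = 0L)
  x <- series$ratio
  n <- length(x)
  if (n < 1) stop("empty ratio series", call. = FALSE)
  half_lo <- window %/% 2
  half_hi <- window - half_lo - 1
  keep <- logical(n)
  se <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - half_lo):min(n, i + half_hi)]
    m <- mean(w)
    s <- stats::sd(w)
    keep[i] <- !(abs(x[i] - m) > k * s)
    se[i] <- s / sqrt(length(w))
  }
  n_rejected <- sum(!keep)
  if (n_rejected / n > max_reject_frac)
    stop(sprintf("outlier rejection removed %.0f%% of points; run quality unacceptable",
                 100 * n_rejected / n), call. = FALSE)
  out <- series[keep & series$distance_um >= 0, , drop = FALSE]
  prof <- data.frame(fish_id = out$fish_id, distance_um = out$distance_um,
                     ratio = out$ratio, se = se[keep & series$distance_um >= 0],
                     stringsAsFactors = FALSE)
  isotope_profile(prof, n_rejected = n_rejected,
                  n_dropped = attr(series, "n_dropped") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct / validate an isotope profile
#'
#' @param prof data frame `fish_id`, `distance_um`, `ratio`, `se`
#' @param n_rejected,n_dropped counts carried from the reduction steps
#' @param sanity_band retained ratios must fall inside this open interval
#' @return object of class `"isotope_profile"`
#' @export
isotope_profile <- function(prof, n_rejected = 0L, n_dropped = 0L,
                            sanity_band = c(0.68, 0.72)) {
  stopifnot(all(c("fish_id", "distance_um", "ratio", "se") %in% names(prof)))
  if (is.unsorted(prof$distance_um) || any(prof$distance_um < 0))
    stop("profile distances must be non-negative and increasing", call. = FALSE)
  if (any(!is.finite(prof$ratio)) ||
      any(prof$ratio <= sanity_band[1] | prof$ratio >= sanity_band[2]))
    stop("retained ratios outside the (", sanity_band[1], ", ",
         sanity_band[2], ") sanity band", call. = FALSE)
  structure(as.data.frame(prof), class = c("isotope_profile", "data.frame"),
            n_rejected = n_rejected, n_dropped = n_dropped)
}

#' @export
print.isotope_profile <- function(x, ...) {
  cat(sprintf("Isotope profile %s: %d points, %.0f-%.0f µm, ratio %.5f-%.5f (%d outliers rejected)\n",
              x$fish_id[1], nrow(x), min(x$distance_um), max(x$distance_um),
              min(x$ratio), max(x$ratio), attr(x, "n_rejected")))
  invisible(x)
}

#' Full reduction of a raw run
#'
#' Composition of [subtract_blank()], [correct_rb()],
#' [normalize_mass_bias()] and [reject_outliers()], in that order.
#'
#' @inheritParams reject_outliers
#' @param run an [ablation_run()]
#' @return an `"isotope_profile"` with a per-step `log` attribute
#' @export
reduce_run <- function(run, window = 40, k = 2) {
  run <- subtract_blank(run)
  run <- correct_rb(run)
  series <- normalize_mass_bias(run)
  prof <- reject_outliers(series, window = window, k = k)
  attr(prof, "log") <- list(n_cycles = nrow(run),
                            n_clipped = attr(run, "n_clipped"),
                            n_dropped = attr(series, "n_dropped"),
                            n_rejected = attr(prof, "n_rejected"),
                            mean_beta = attr(series, "mean_beta"))
  prof
}
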