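# Ground-truthed synthetic cohorts: piecewise salinity life histories for the
# three phenotypes, forward-modelled 87Sr/86Sr chronologies, daily otolith
# increments, raw laser-ablation intensity runs, and gonad-maturity tables.

#' Parameters for a synthetic cohort
#'
#' Defaults describe an estuarine smelt-like cohort: mostly semi-anadromous
#' fish (81%) with four dispersal-age sub-types centred at 113, 93, 72 and
#' 51 days, a freshwater-resident minority (12%) and a brackish-water-resident
#' minority (7%). Salinity levels are drawn per fish from the stated PSU
#' ranges; fresh natal habitat sits well below the 0.5 PSU boundary and
#' brackish habitat well above it.
#'
#' @param n_fish cohort size
#' @param phenotype_probs probabilities of (FWR, BWR, SA); must sum to 1
#' @param sa_dispersal_age_means,sa_dispersal_age_sd means and SDs (days) of
#'   the normal dispersal-age distributions of the SA sub-types
#' @param sa_subtype_probs sampling probabilities of the SA sub-types
#' @param natal_salinity_fresh,natal_salinity_brackish PSU ranges for natal
#'   habitat of freshwater-hatching (FWR, SA) and brackish-hatching (BWR) fish
#' @param adult_salinity_sa,adult_salinity_bwr PSU ranges for post-dispersal /
#'   adult habitat
#' @param age_at_capture_range integer range of ages at capture, days
#' @param increment_width_mean,increment_width_sd lognormal daily otolith
#'   increment widths, µm/day
#' @param salinity_jitter_sd,salinity_jitter_phi log-scale SD and AR(1)
#'   coefficient of the day-to-day salinity jitter
#' @param transition_width_days 10--90% width of the logistic
#'   freshwater-to-brackish salinity transition of SA fish
#' @param dispersal_truncation days from either end of life within which a
#'   drawn dispersal age is not allowed to fall (avoids degenerate
#'   changepoint geometry)
#' @param ratio_noise_sd target SD of the per-cycle measured 87Sr/86Sr in the
#'   simulated ablation signal (dimensionless ratio units)
#' @param seed integer RNG seed
#' @return an object of class `"cohort_params"`
#' @export
cohort_params <- function(n_fish = 285,
                          phenotype_probs = c(FWR = 0.12, BWR = 0.07, SA = 0.81),
                          sa_dispersal_age_means = c(113, 93, 72, 51),
                          sa_dispersal_age_sd = c(20, 20, 8, 8),
                          sa_subtype_probs = NULL,
                          natal_salinity_fresh = c(0.05, 0.2),
                          natal_salinity_brackish = c(2, 4),
                          adult_salinity_sa = c(2, 4),
                          adult_salinity_bwr = c(2, 4),
                          age_at_capture_range = c(180, 240),
                          increment_width_mean = 2, increment_width_sd = 0.3,
                          salinity_jitter_sd = 0.03, salinity_jitter_phi = 0.9,
                          transition_width_days = 5,
                          dispersal_truncation = 20,
                          ratio_noise_sd = 1e-4,
                          seed = 1L) {
  if (length(phenotype_probs) != 3 || any(phenotype_probs < 0) ||
      any(phenotype_probs > 1) || abs(sum(phenotype_probs) - 1) > 1e-12)
    stop("phenotype_probs must be three probabilities summing to 1",
         call. = FALSE)
  stopifnot(n_fish >= 1,
            length(sa_dispersal_age_means) == length(sa_dispersal_age_sd),
            all(sa_dispersal_age_sd >= 0), increment_width_sd >= 0,
            salinity_jitter_sd >= 0, ratio_noise_sd >= 0,
            age_at_capture_range[1] >= 2 * dispersal_truncation)
  if (is.null(sa_subtype_probs))
    sa_subtype_probs <- rep(1 / length(sa_dispersal_age_means),
                            length(sa_dispersal_age_means))
  p <- as.list(environment())
  names(p$phenotype_probs) <- c("FWR", "BWR", "SA")
  class(p) <- "cohort_params"
  p
}

ar1_log_jitter <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(rep(0, n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Simulate one true salinity/ratio chronology
#'
#' Residents (FWR, BWR) get a near-constant salinity with multiplicative
#' AR(1) jitter; semi-anadromous fish get a logistic freshwater-to-brackish
#' transition whose 0.5 PSU crossing falls exactly on the true dispersal age.
#' The daily ratio is always the exact forward mixing transform of the daily
#' salinity, so downstream stages can be scored against machine-precision
#' truth. Phenotype salinity-side invariants (FWR < 0.5 PSU throughout,
#' BWR >= 0.5 throughout, SA fresh before / brackish from the dispersal age)
#' are enforced by clamping at the boundary, which only ever bites within the
#' few transition days when jitter is non-zero.
#'
#' @param phenotype one of "FWR", "BWR", "SA"
#' @param age_at_capture age at capture, days (chronology covers ages
#'   `0..age_at_capture`)
#' @param natal_salinity,adult_salinity habitat levels, PSU
#' @param dispersal_age SA only: day of the freshwater-to-brackish crossing
#' @param params a [cohort_params()] object (jitter and transition settings)
#' @param mixing calibrated [mixing_params()]
#' @return list with `salinity` and `ratio`, each of length
#'   `age_at_capture + 1` (ages 0..T)
#' @export
simulate_true_chronology <- function(phenotype, age_at_capture,
                                     natal_salinity, adult_salinity = natal_salinity,
                                     dispersal_age = NA,
                                     params = cohort_params(),
                                     mixing = calibrate_freshwater_endmember()) {
  phenotype <- match.arg(phenotype, c("FWR", "BWR", "SA"))
  stopifnot(age_at_capture >= 1)
  t <- 0:age_at_capture
  if (phenotype == "SA") {
    if (is.na(dispersal_age)) stop("SA fish need a dispersal_age", call. = FALSE)
    stopifnot(natal_salinity < 0.5, adult_salinity >= 0.5)
    s <- params$transition_width_days / 4   # logistic scale; 10-90% span ~ width
    # centre the logistic so S(dispersal_age) = 0.5 PSU exactly
    t0 <- dispersal_age + s * log((adult_salinity - 0.5) / (0.5 - natal_salinity))
    sal <- natal_salinity + (adult_salinity - natal_salinity) *
      stats::plogis((t - t0) / s)
  } else {
    sal <- rep(natal_salinity, length(t))
  }
  sal <- sal * exp(ar1_log_jitter(length(t), params$salinity_jitter_sd,
                                  params$salinity_jitter_phi))
  eps <- 1e-9
  sal <- switch(phenotype,
    FWR = pmin(sal, 0.5 - eps),
    BWR = pmax(sal, 0.5),
    SA  = ifelse(t < dispersal_age, pmin(sal, 0.5 - eps), pmax(sal, 0.5)))
  list(salinity = sal, ratio = ratio_from_salinity(sal, mixing))
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate a ground-truthed cohort
#'
#' Draws phenotypes, ages, habitat salinities, dispersal ages, daily
#' increment widths and true chronologies for `n_fish` fish. Identical seeds
#' give bit-identical cohorts.
#'
#' @param params a [cohort_params()] object
#' @param mixing calibrated [mixing_params()]
#' @return an object of class `"sr_cohort"`: a list of fish, each a list with
#'   `fish_id`, `phenotype`, `sa_subtype`, `dispersal_age`, `age_at_capture`,
#'   `salinity`, `ratio` (ages 0..T) and `increments` (days 1..T, µm)
#' @export
simulate_cohort <- function(params = cohort_params(),
                            mixing = calibrate_freshwater_endmember()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_fish
  phen <- sample(c("FWR", "BWR", "SA"), n, replace = TRUE,
                 prob = params$phenotype_probs)
  ages <- sample(seq(params$age_at_capture_range[1],
                     params$age_at_capture_range[2]), n, replace = TRUE)
  fish <- vector("list", n)
  for (i in seq_len(n)) {
    T_i <- ages[i]
    subtype <- NA_integer_
    tau <- NA_real_
    if (phen[i] == "SA") {
      subtype <- sample.int(length(params$sa_dispersal_age_means), 1,
                            prob = params$sa_subtype_probs)
      tau <- round(stats::rnorm(1, params$sa_dispersal_age_means[subtype],
                                params$sa_dispersal_age_sd[subtype]))
      tau <- min(max(tau, params$dispersal_truncation),
                 T_i - params$dispersal_truncation)
    }
    natal <- if (phen[i] == "BWR")
      runif_range(1, params$natal_salinity_brackish)
    else runif_range(1, params$natal_salinity_fresh)
    adult <- switch(phen[i],
                    FWR = natal,
                    BWR = runif_range(1, params$adult_salinity_bwr),
                    SA = runif_range(1, params$adult_salinity_sa))
    if (phen[i] == "BWR") adult <- natal  # residents hold their habitat
    chron <- simulate_true_chronology(phen[i], T_i, natal, adult, tau,
                                      params, mixing)
    widths <- stats::rlnorm(T_i,
                            meanlog = log(params$increment_width_mean^2 /
                              sqrt(params$increment_width_mean^2 +
                                     params$increment_width_sd^2)),
                            sdlog = sqrt(log(1 + params$increment_width_sd^2 /
                                               params$increment_width_mean^2)))
    fish[[i]] <- list(fish_id = sprintf("F%03d", i), phenotype = phen[i],
                      sa_subtype = subtype, dispersal_age = tau,
                      age_at_capture = T_i,
                      salinity = chron$salinity, ratio = chron$ratio,
                      increments = widths)
  }
  structure(fish, class = "sr_cohort", params = params)
}

#' @export
print.sr_cohort <- function(x, ...) {
  phen <- vapply(x, `[[`, "", "phenotype")
  cat(sprintf("Synthetic otolith cohort: %d fish (%s)\n", length(x),
              paste(sprintf("%s %d", names(table(phen)), table(phen)),
                    collapse = ", ")))
  invisible(x)
}

# exact Sr/Rb atomic masses (amu) and canonical ratios used throughout
sr_masses <- c(m84 = 83.913425, m85 = 84.9117897, m86 = 85.9092607,
               m87 = 86.9088775, m88 = 87.9056123)
SR88_86_NATURAL <- 8.375     # natural 88Sr/86Sr abundance ratio
SR86_88_CANONICAL <- 0.1194  # canonical 86Sr/88Sr for mass-bias normalization
SR84_86_NATURAL <- 0.0565
RB87_85_NATURAL <- 0.385710

#' Simulate a raw laser-ablation run for one fish
#'
#' Emulates a transect at `scan_speed` µm/s starting `core_offset_um` before
#' the core and ending at the otolith edge, preceded by a gas-blank segment.
#' Cumulative daily increment widths map age to radius; the true daily ratio
#' is interpolated onto each cycle's position. Per-cycle intensities on
#' masses 84/85/86/87/88 honour natural Sr abundances (88/86 = 8.375), carry
#' an optional Rb contamination on mass 85/87, are distorted by an
#' exponential per-amu mass-bias factor, and receive multiplicative lognormal
#' noise scaled so the measured per-cycle 87Sr/86Sr SD is about
#' `ratio_noise_sd` (plasma-flicker-dominated noise, not shot noise).
#'
#' @param fish one element of an [simulate_cohort()] cohort
#' @param ratio_noise_sd per-cycle 87Sr/86Sr noise SD
#' @param mass_bias_per_amu instrumental bias factor per amu (1 = none)
#' @param rb_contamination Rb contribution to mass 87 as a fraction of the
#'   87Sr signal
#' @param i88_cps mass-88 ablation signal level, counts per second
#' @param blank_cps gas-blank level added to every mass channel, cps
#' @param blank_s leading gas-blank duration, s
#' @param dt cycle integration time, s
#' @param scan_speed laser traverse speed, µm/s
#' @param spot_diameter_um laser spot, µm (metadata)
#' @param core_offset_um distance from ablation start to the core crossing
#' @return an `"ablation_run"`: data frame of cycles (`time_s`, `i84`..`i88`,
#'   `segment`) with scan-geometry attributes
#' @export
simulate_ablation_run <- function(fish, ratio_noise_sd = 1e-4,
                                  mass_bias_per_amu = 1.002,
                                  rb_contamination = 0.01,
                                  i88_cps = 1e6, blank_cps = 100,
                                  blank_s = 20, dt = 0.25,
                                  scan_speed = 10, spot_diameter_um = 40,
                                  core_offset_um = 100) {
  if (length(fish$increments) == 0 || any(fish$increments <= 0))
    stop("fish has no valid increment series; cannot lay out scan geometry",
         call. = FALSE)
  radius_edge <- sum(fish$increments)
  total_s <- blank_s + (core_offset_um + radius_edge) / scan_speed
  time_s <- seq(dt, total_s, by = dt)
  pos_um <- (time_s - blank_s) * scan_speed - core_offset_um  # from core
  segment <- ifelse(time_s <= blank_s, "blank",
                    ifelse(pos_um < 0, "precore", "ablation"))
  n_cyc <- length(time_s)

  true_ratio <- stats::approx(x = c(0, cumsum(fish$increments)),
                              y = fish$ratio, xout = pmax(pos_um, 0),
                              rule = 2)$y
  on_otolith <- segment == "ablation"
  i86 <- ifelse(on_otolith, i88_cps * SR86_88_CANONICAL, 0)
  i88 <- ifelse(on_otolith, i88_cps, 0)
  i87sr <- i86 * true_ratio * on_otolith
  i84 <- i86 * SR84_86_NATURAL
  i87rb <- rb_contamination * i87sr
  i85 <- i87rb / RB87_85_NATURAL
  i87 <- i87sr + i87rb

  bias <- function(m) mass_bias_per_amu^(sr_masses[[m]] - sr_masses[["m86"]])
  sig <- cbind(i84 = i84 * bias("m84"), i85 = i85 * bias("m85"),
               i86 = i86, i87 = i87 * bias("m87"), i88 = i88 * bias("m88"))

  # lognormal flicker: ratio of two channels has sd ~ sqrt(2)*s*ratio
  s <- ratio_noise_sd / (0.7075 * sqrt(2))
  noisy <- sig + blank_cps
  if (s > 0)
    noisy <- noisy * matrix(exp(stats::rnorm(5L * n_cyc, -s^2 / 2, s)),
                            n_cyc, 5)
  run <- data.frame(fish_id = fish$fish_id, cycle = seq_len(n_cyc),
                    time_s = time_s, noisy, segment = segment,
                    stringsAsFactors = FALSE)
  ablation_run(run, scan_speed = scan_speed,
               spot_diameter_um = spot_diameter_um,
               core_offset_um = core_offset_um)
}

#' Simulate a gonad-maturity survey table
#'
#' Draws binary late-stage (IV--VI) outcomes from a logistic surface over
#' centred Julian date, sex and capture region with all interactions, then
#' assigns a concrete stage (I--III early, IV--VI late). Julian dates are
#' uniform over 1..151 (January--May); sexes and regions are balanced.
#'
#' @param n number of fish
#' @param coefficients named coefficient vector on the treatment-coded design
#'   `~ jd_c * sex * region` with references sex `F` and region `SP-S`, where
#'   `jd_c` is Julian date minus 76 (the window midpoint). Missing names
#'   default to 0.
#' @param seed RNG seed
#' @return data frame of `MaturityRecord`s: `fish_id`, `sex`, `region`,
#'   `julian_date`, `stage`, `late`
#' @export
simulate_maturity_table <- function(n = 1025, coefficients = NULL, seed = 1L) {
  set.seed(seed)
  sex <- factor(rep_len(c("F", "M"), n), levels = c("F", "M"))
  region <- factor(rep_len(c("SP-S", "W-CD", "ND"), n),
                   levels = c("SP-S", "W-CD", "ND"))
  jd <- sample.int(151, n, replace = TRUE)
  X <- stats::model.matrix(~ jd_c * sex * region,
                           data.frame(jd_c = jd - 76, sex = sex,
                                      region = region))
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(coefficients)) {
    unknown <- setdiff(names(coefficients), colnames(X))
    if (length(unknown))
      stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    beta[names(coefficients)] <- coefficients
  }
  p_late <- stats::plogis(drop(X %*% beta))
  late <- stats::rbinom(n, 1, p_late)
  stage <- ifelse(late == 1, sample(c("IV", "V", "VI"), n, replace = TRUE),
                  sample(c("I", "II", "III"), n, replace = TRUE))
  data.frame(fish_id = sprintf("M%04d", seq_len(n)), sex = sex,
             region = region, julian_date = jd,
             stage = factor(stage, levels = c("I", "II", "III", "IV", "V", "VI")),
             late = late, stringsAsFactors = FALSE)
}
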