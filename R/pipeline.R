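# End-to-end orchestration and CSV plumbing: simulate -> reduce ->
# chronology -> salinity -> classify -> cluster -> validate.

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Long/wide chronology table conversion
#'
#' Clustering needs a fish-by-age matrix; storage and joins prefer long
#' form. The two conversions are exact inverses.
#'
#' @param chrons list of `sr_chronology` objects
#' @return `chronologies_long`: data frame `fish_id`, `age`, `ratio`,
#'   `salinity`; `chronologies_wide`: data frame `fish_id`, `age_0` ...
#' @export
chronologies_long <- function(chrons) {
  do.call(rbind, c(lapply(chrons, function(ch)
    data.frame(fish_id = attr(ch, "fish_id"), age = ch$age,
               ratio = ch$ratio, salinity = ch$salinity,
               stringsAsFactors = FALSE)), list(make.row.names = FALSE)))
}

#' @rdname chronologies_long
#' @export
chronologies_wide <- function(chrons) {
  lens <- vapply(chrons, nrow, 0L)
  if (length(unique(lens)) != 1)
    stop("wide form needs equal-length chronologies", call. = FALSE)
  m <- t(vapply(chrons, function(ch) ch$ratio, numeric(lens[1])))
  out <- data.frame(fish_id = vapply(chrons, attr, "", "fish_id"), m,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("fish_id", paste0("age_", chrons[[1]]$age))
  out
}

#' @param long data frame in the long dialect
#' @rdname chronologies_long
#' @export
chronologies_from_long <- function(long) {
  check_columns(long, c("fish_id", "age", "ratio"), "long chronology table")
  if (is.null(long$salinity)) long$salinity <- NA_real_
  lapply(split(long, long$fish_id), function(d)
    sr_chronology(d[order(d$age), c("age", "ratio", "salinity")],
                  fish_id = d$fish_id[1]))
}

#' Read / write the pipeline's CSV schemas
#'
#' Plain RFC-4180 CSV with validated headers. `runs`: one row per cycle
#' (`fish_id`, `cycle`, `time_s`, `i84`..`i88`, `segment`); `increments`:
#' (`fish_id`, `age_day`, `width_um`); `truth`: per-fish ground truth;
#' `profiles`: (`fish_id`, `distance_um`, `ratio`, `se`); `calls`, and
#' `maturity` tables as produced by the corresponding stages.
#'
#' @param x object to write
#' @param path file path
#' @name pipeline_csv
#' @export
write_runs_csv <- function(x, path) {
  runs <- if (inherits(x, "ablation_run")) list(x) else x
  utils::write.csv(do.call(rbind, lapply(runs, as.data.frame)), path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_csv
#' @export
read_runs_csv <- function(path, scan_speed = 10, spot_diameter_um = 40,
                          core_offset_um = 100) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("fish_id", "time_s", "i84", "i85", "i86", "i87", "i88",
                     "segment"), "runs CSV")
  lapply(split(d, d$fish_id), ablation_run, scan_speed = scan_speed,
         spot_diameter_um = spot_diameter_um,
         core_offset_um = core_offset_um)
}

#' @rdname pipeline_csv
#' @export
write_increments_csv <- function(cohort, path) {
  long <- do.call(rbind, lapply(cohort, function(f)
    data.frame(fish_id = f$fish_id, age_day = seq_along(f$increments),
               width_um = f$increments)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_csv
#' @export
read_increments_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("fish_id", "age_day", "width_um"), "increments CSV")
  lapply(split(d, d$fish_id), function(x) x$width_um[order(x$age_day)])
}

#' @rdname pipeline_csv
#' @export
write_truth_csv <- function(cohort, path) {
  utils::write.csv(data.frame(
    fish_id = vapply(cohort, `[[`, "", "fish_id"),
    phenotype = vapply(cohort, `[[`, "", "phenotype"),
    sa_subtype = vapply(cohort, `[[`, 0L, "sa_subtype"),
    dispersal_age = vapply(cohort, `[[`, 0, "dispersal_age"),
    age_at_capture = vapply(cohort, `[[`, 0L, "age_at_capture")),
    path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(do.call(rbind, lapply(profiles, as.data.frame)), path,
                   row.names = FALSE, quote = FALSE)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings; validated up front so a bad configuration
#' fails before any stage runs.
#'
#' @param params [cohort_params()] for the synthetic cohort
#' @param mixing [mixing_params()] (calibrated here if not already)
#' @param threshold,natal_window supervised classification settings
#' @param trim chronology trim length for clustering, days
#' @param k cluster count
#' @param n_perm PERMANOVA permutations
#' @param spline_df alignment spline degrees of freedom
#' @param salinity_tol ratio clamping tolerance for the salinity conversion;
#'   wider than the point-measurement default because a df-10 spline can
#'   overshoot the freshwater endmember near a sharp habitat transition
#' @param out_dir optional directory for stage CSVs
#' @return object of class `"pipeline_config"`
#' @export
pipeline_config <- function(params = cohort_params(),
                            mixing = mixing_params(),
                            threshold = 0.7075, natal_window = 30,
                            trim = 170, k = 6, n_perm = 999,
                            spline_df = 10, salinity_tol = 5e-4,
                            out_dir = NULL) {
  stopifnot(inherits(params, "cohort_params"), inherits(mixing, "sr_mixing"))
  if (is.null(mixing$anchor_ratio) || is.null(mixing$anchor_salinity))
    stop("mixing configuration lacks an anchor point", call. = FALSE)
  structure(list(params = params, mixing = mixing, threshold = threshold,
                 natal_window = natal_window, trim = trim, k = k,
                 n_perm = n_perm, spline_df = spline_df,
                 salinity_tol = salinity_tol, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full reconstruction pipeline on a synthetic cohort
#'
#' Simulates a ground-truthed cohort, renders and reduces ablation runs,
#' builds daily chronologies and salinity tracks, assigns supervised
#' phenotypes with dispersal ages, trims and clusters the chronologies, and
#' (when group sizes allow) validates the SA clusters with PERMANOVA and
#' jackknifed QDA. Everything is a pure function of the configuration, whose
#' seed drives all randomness; the manifest records per-stage counts,
#' exclusions and (when `out_dir` is set) output-file MD5 hashes.
#'
#' @param config a [pipeline_config()]
#' @return list of class `"lh_pipeline"` with elements `cohort`, `profiles`,
#'   `chronologies`, `calls`, `labels`, `attributes`, `stats`, `manifest`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  mixing <- if (is.na(config$mixing$R_fresh))
    calibrate_freshwater_endmember(config$mixing) else config$mixing

  cohort <- simulate_cohort(config$params, mixing)
  set.seed(config$params$seed + 1L)  # measurement-noise stream
  runs <- lapply(cohort, simulate_ablation_run,
                 ratio_noise_sd = config$params$ratio_noise_sd)
  profiles <- lapply(runs, reduce_run)
  chrons <- lapply(seq_along(cohort), function(i) {
    ch <- align_profile(profiles[[i]], build_age_map(cohort[[i]]$increments),
                        df = config$spline_df)
    suppressWarnings(chronology_to_salinity(ch, mixing,
                                            tol = config$salinity_tol))
  })
  names(chrons) <- vapply(cohort, `[[`, "", "fish_id")
  calls <- classify_cohort(chrons, threshold = config$threshold,
                           natal_window = config$natal_window)

  excluded <- character()
  trimmed <- list()
  for (ch in chrons) {
    t <- tryCatch(trim_chronology(ch, config$trim),
                  otolithsr_exclusion = function(e) e)
    if (inherits(t, "condition")) excluded <- c(excluded, conditionMessage(t))
    else trimmed[[attr(ch, "fish_id")]] <- t
  }
  labels <- NULL
  if (length(trimmed) >= config$k)
    labels <- cut_tree(ward_cluster(pairwise_distances(dwt_features(trimmed))),
                       k = config$k)

  attributes <- build_attribute_table(
    trimmed, calls[calls$fish_id %in% names(trimmed), ])
  sa <- attributes[attributes$phenotype == "SA" &
                     is.finite(attributes$dispersal_age), ]
  stats_out <- list()
  if (!is.null(labels) && nrow(sa) > 10) {
    sa_lab <- labels[sa$fish_id]
    keep_groups <- names(which(table(sa_lab) >= 5))
    idx <- sa_lab %in% keep_groups
    if (length(keep_groups) >= 2) {
      X <- sa[idx, c("natal_mean", "post_mean", "dispersal_age")]
      stats_out$permanova <- permanova(X, sa_lab[idx],
                                       n_perm = config$n_perm,
                                       seed = config$params$seed + 2L)
      stats_out$qda <- tryCatch(qda_jackknife(X, sa_lab[idx]),
                                error = function(e) NULL)
    }
  }

  truth <- vapply(cohort, `[[`, "", "phenotype")
  recovery <- mean(calls$phenotype == truth)
  sa_true <- vapply(cohort, `[[`, 0, "dispersal_age")
  sa_idx <- which(truth == "SA" & calls$phenotype == "SA")
  disp_mae <- if (length(sa_idx))
    stats::median(abs(calls$dispersal_age[sa_idx] - sa_true[sa_idx]),
                  na.rm = TRUE) else NA_real_

  manifest <- list(seed = config$params$seed,
                   n_fish = length(cohort),
                   n_profiles = length(profiles),
                   n_chronologies = length(chrons),
                   n_trimmed = length(trimmed),
                   n_excluded = length(excluded),
                   exclusions = excluded,
                   phenotype_recovery = recovery,
                   sa_dispersal_median_abs_error = disp_mae,
                   phenotype_percent = phenotype_proportions(calls$phenotype))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(runs = file.path(config$out_dir, "runs.csv"),
               increments = file.path(config$out_dir, "increments.csv"),
               truth = file.path(config$out_dir, "truth.csv"),
               profiles = file.path(config$out_dir, "profiles.csv"),
               chronologies = file.path(config$out_dir, "chronologies.csv"),
               calls = file.path(config$out_dir, "calls.csv"))
    write_runs_csv(runs, paths["runs"])
    write_increments_csv(cohort, paths["increments"])
    write_truth_csv(cohort, paths["truth"])
    write_profiles_csv(profiles, paths["profiles"])
    utils::write.csv(chronologies_long(chrons), paths["chronologies"],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(calls), paths["calls"], row.names = FALSE,
                     quote = FALSE)
    manifest$output_md5 <- tools::md5sum(paths)
  }
  structure(list(cohort = cohort, profiles = profiles,
                 chronologies = chrons, calls = calls, labels = labels,
                 attributes = attributes, stats = stats_out,
                 manifest = manifest),
            class = "lh_pipeline")
}

#' @export
print.lh_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Life-history pipeline run (seed %d)\n", m$seed))
  cat(sprintf("  %d fish -> %d chronologies, %d trimmed for clustering (%d excluded)\n",
              m$n_fish, m$n_chronologies, m$n_trimmed, m$n_excluded))
  cat(sprintf("  phenotype recovery vs truth: %.1f%%; SA dispersal-age median |error|: %.1f d\n",
              100 * m$phenotype_recovery, m$sa_dispersal_median_abs_error))
  cat("  phenotype percentages: ",
      paste(names(m$phenotype_percent), m$phenotype_percent, sep = " ",
            collapse = ", "), "\n")
  invisible(x)
}
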