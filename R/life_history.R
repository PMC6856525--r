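# Supervised life-history assignment: threshold classification into
# freshwater-resident (FWR), brackish-water-resident (BWR) and
# semi-anadromous (SA) phenotypes, at-most-one-changepoint (AMOC) dispersal
# age estimation, and the three-attribute table used for validation.

#' Natal and post-dispersal window means
#'
#' Arithmetic means of the daily ratio over the closed age windows
#' `[0, 30]` (natal origin) and `[140, 170]` (post-dispersal).
#'
#' @param chron an `sr_chronology`
#' @param from,to closed age window, days
#' @return mean 87Sr/86Sr over the window
#' @export
window_mean <- function(chron, from, to) {
  stopifnot(inherits(chron, "sr_chronology"))
  if (min(chron$age) > from || max(chron$age) < to)
    stop("chronology does not cover ages [", from, ", ", to, "]",
         call. = FALSE)
  mean(chron$ratio[chron$age >= from & chron$age <= to])
}

#' @rdname window_mean
#' @export
natal_mean <- function(chron, from = 0, to = 30) window_mean(chron, from, to)

#' @rdname window_mean
#' @export
post_dispersal_mean <- function(chron, from = 140, to = 170) {
  # a 170-day trimmed chronology ends at age 169; the window closes there
  window_mean(chron, from, min(to, max(chron$age)))
}

#' Threshold life-history classification
#'
#' A fish is freshwater resident when its whole profile stays below the
#' threshold, brackish-water resident when the natal period (first
#' `natal_window` days) already sits above it, and semi-anadromous when the
#' natal period is fresh but the fish later moves above the threshold. "Later
#' moves above" is operationalized noise-robustly as at least `min_run`
#' consecutive post-natal days above the threshold; the final `edge_exclude`
#' days are left out of every comparison because otolith-edge chemistry can
#' record late return movements that this scheme deliberately ignores.
#'
#' @param chron an `sr_chronology`
#' @param threshold 87Sr/86Sr separating fresh from brackish rearing
#'   (default 0.7075, the 0.5 PSU boundary under the calibrated mixing model)
#' @param natal_window natal period length, days (default 30)
#' @param min_run consecutive days above threshold required to call a
#'   dispersal (default 10)
#' @param edge_exclude days dropped at the capture end (default 5)
#' @param borderline_tol flag natal means within this distance of the
#'   threshold as borderline
#' @return list with `phenotype` ("FWR"/"BWR"/"SA"), `natal_mean`, and
#'   logical `borderline`
#' @export
classify_threshold <- function(chron, threshold = 0.7075, natal_window = 30,
                               min_run = 10, edge_exclude = 5,
                               borderline_tol = 2e-5) {
  stopifnot(inherits(chron, "sr_chronology"))
  T_last <- max(chron$age)
  if (T_last < natal_window + 10)
    stop("chronology too short to classify", call. = FALSE)
  used <- chron[chron$age <= T_last - edge_exclude, , drop = FALSE]
  nm <- mean(used$ratio[used$age <= natal_window])
  post <- used$ratio[used$age > natal_window]
  run_above <- with(rle(post > threshold), max(c(0, lengths[values])))
  phenotype <- if (nm >= threshold) "BWR"
  else if (run_above >= min_run) "SA"
  else "FWR"
  borderline <- abs(nm - threshold) <= borderline_tol
  if (borderline)
    warning("natal mean within ", borderline_tol,
            " of the threshold; classification is borderline")
  list(phenotype = phenotype, natal_mean = nm, borderline = borderline)
}

#' At-most-one-changepoint dispersal age
#'
#' Single mean-shift changepoint under a normal likelihood with pooled
#' variance: for each admissible split the statistic is
#' `n * log(RSS0 / RSS1(tau))`, twice the profile log-likelihood ratio of the
#' two-mean against the one-mean model. The maximizing split is reported; a
#' Schwarz-type penalty (`2 log n` by default) decides whether a changepoint
#' is declared at all. The returned age is the first day of the post-change
#' segment (ages starting at 0), i.e. the age at dispersal for an SA fish.
#'
#' @param chron an `sr_chronology` or numeric series
#' @param min_segment minimum days on either side of the changepoint
#' @param penalty statistic threshold below which "no changepoint" is
#'   returned (default `2 * log(n)`)
#' @return list with `age` (NA when no changepoint), `statistic`, and the
#'   `penalty` used
#' @export
detect_dispersal_age <- function(chron, min_segment = 10, penalty = NULL) {
  x <- if (inherits(chron, "sr_chronology")) chron$ratio else as.numeric(chron)
  ages <- if (inherits(chron, "sr_chronology")) chron$age else seq_along(x) - 1
  n <- length(x)
  if (n < 2 * min_segment + 1)
    stop("series too short for min_segment = ", min_segment, call. = FALSE)
  if (is.null(penalty)) penalty <- 2 * log(n)
  x <- x - mean(x)  # centring avoids catastrophic cancellation in the RSS
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  rss0 <- max(cs2[n] - cs[n]^2 / n, 0)
  if (rss0 < n * .Machine$double.eps)  # flat series: nothing to detect
    return(list(age = NA_real_, statistic = 0, penalty = penalty))
  taus <- min_segment:(n - min_segment)  # last index of the first segment
  rss1 <- (cs2[taus] - cs[taus]^2 / taus) +
    (cs2[n] - cs2[taus] - (cs[n] - cs[taus])^2 / (n - taus))
  stat <- n * log(rss0 / pmax(rss1, .Machine$double.eps * n))
  stat[!is.finite(stat)] <- -Inf
  best <- which.max(stat)
  if (!is.finite(stat[best]) || stat[best] < penalty)
    return(list(age = NA_real_, statistic = max(0, stat[best]),
                penalty = penalty))
  list(age = ages[taus[best] + 1], statistic = stat[best], penalty = penalty)
}

#' Life-history attribute table
#'
#' One row per fish with the three attributes used for cluster validation:
#' natal-window mean, post-dispersal-window mean, and dispersal age
#' (undefined for the two resident phenotypes).
#'
#' @param chrons named list of `sr_chronology` objects
#' @param calls data frame with `fish_id` and `phenotype` (e.g. from
#'   [classify_cohort()])
#' @param ... window settings passed to [natal_mean()] /
#'   [post_dispersal_mean()] and [detect_dispersal_age()]
#' @return data frame `fish_id`, `phenotype`, `natal_mean`, `post_mean`,
#'   `dispersal_age`
#' @export
build_attribute_table <- function(chrons, calls, ...) {
  if (length(chrons) == 0)
    return(data.frame(fish_id = character(), phenotype = character(),
                      natal_mean = numeric(), post_mean = numeric(),
                      dispersal_age = numeric()))
  ids <- vapply(chrons, attr, "", "fish_id")
  if (anyDuplicated(ids)) stop("duplicated fish_id", call. = FALSE)
  if (!all(ids %in% calls$fish_id))
    stop("chronologies and calls cover different fish", call. = FALSE)
  phen <- calls$phenotype[match(ids, calls$fish_id)]
  tab <- data.frame(fish_id = ids, phenotype = phen,
                    natal_mean = vapply(chrons, natal_mean, 0),
                    post_mean = vapply(chrons, post_dispersal_mean, 0),
                    dispersal_age = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in which(phen == "SA"))
    tab$dispersal_age[i] <- detect_dispersal_age(chrons[[i]])$age
  tab
}

#' Classify every fish in a set of chronologies
#'
#' Applies [classify_threshold()] to each chronology and, for SA fish,
#' [detect_dispersal_age()]. An SA call whose changepoint statistic falls
#' below the penalty is kept but flagged as discordant.
#'
#' @param chrons list of `sr_chronology` objects
#' @param ... passed to [classify_threshold()]
#' @return data frame of calls: `fish_id`, `phenotype`, `natal_mean`,
#'   `post_mean`, `dispersal_age`, `borderline`, `discordant`
#' @export
classify_cohort <- function(chrons, ...) {
  rows <- lapply(chrons, function(ch) {
    cl <- suppressWarnings(classify_threshold(ch, ...))
    disp <- NA_real_
    discordant <- FALSE
    if (cl$phenotype == "SA") {
      cp <- detect_dispersal_age(ch)
      disp <- cp$age
      discordant <- is.na(cp$age)
    }
    data.frame(fish_id = attr(ch, "fish_id"), phenotype = cl$phenotype,
               natal_mean = cl$natal_mean,
               post_mean = tryCatch(post_dispersal_mean(ch),
                                    error = function(e) NA_real_),
               dispersal_age = disp, borderline = cl$borderline,
               discordant = discordant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("lh_calls", "data.frame")
  out
}

#' @export
print.lh_calls <- function(x, ...) {
  cat("Life-history calls:\n")
  print(table(x$phenotype))
  invisible(x)
}
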