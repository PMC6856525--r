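# Unsupervised life-history grouping: level-1 Haar DWT approximation
# features of equal-length chronologies, Euclidean distances, Ward
# agglomerative clustering, fixed-k cut, and cluster summaries.

#' Level-1 Haar approximation coefficients
#'
#' Orthonormal convention: `a_k = (x[2k-1] + x[2k]) / sqrt(2)`. Together with
#' the discarded detail band `d_k = (x[2k-1] - x[2k]) / sqrt(2)` this is an
#' orthogonal transform, so Parseval holds and distances on the
#' approximation band can only shrink relative to the raw series.
#'
#' @param x numeric series of even length
#' @return numeric vector of length `length(x)/2`
#' @export
haar_level1 <- function(x) {
  n <- length(x)
  if (n %% 2 != 0) stop("Haar level-1 needs an even series length",
                        call. = FALSE)
  (x[seq(1, n, 2)] + x[seq(2, n, 2)]) / sqrt(2)
}

#' Haar feature matrix for a cohort of trimmed chronologies
#'
#' @param chrons list of equal-length `sr_chronology` objects (see
#'   [trim_chronology()])
#' @return matrix, one row per fish (rownames = fish ids), `T/2` columns
#' @export
dwt_features <- function(chrons) {
  lens <- vapply(chrons, nrow, 0L)
  if (length(unique(lens)) != 1)
    stop("all chronologies must have the same length for clustering",
         call. = FALSE)
  feats <- t(vapply(chrons, function(ch) haar_level1(ch$ratio),
                    numeric(lens[1] / 2)))
  rownames(feats) <- vapply(chrons, attr, "", "fish_id")
  if (any(!is.finite(feats))) stop("non-finite wavelet coefficients",
                                   call. = FALSE)
  feats
}

#' Euclidean distances between feature vectors
#'
#' @param features matrix from [dwt_features()]
#' @return a `dist` object
#' @export
pairwise_distances <- function(features) {
  if (any(!is.finite(features))) stop("non-finite features", call. = FALSE)
  stats::dist(features, method = "euclidean")
}

#' Ward agglomerative clustering
#'
#' Ward's minimum-variance linkage on Euclidean distances (the
#' Lance-Williams recurrence on squared distances, as implemented by
#' `stats::hclust(method = "ward.D2")`): each merge is the pair of clusters
#' whose fusion least increases the total within-cluster sum of squares.
#'
#' @param d a `dist` object from [pairwise_distances()]
#' @return an `hclust` tree
#' @export
ward_cluster <- function(d) {
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (attr(d, "Size") < 2) stop("need at least 2 fish", call. = FALSE)
  stats::hclust(d, method = "ward.D2")
}

#' Cut the Ward tree into k clusters
#'
#' Labels are renumbered by descending cluster size (ties by first
#' appearance) so cluster 1 is always the largest.
#'
#' @param tree an `hclust` object from [ward_cluster()]
#' @param k number of clusters (default 6)
#' @return integer labels named by fish id
#' @export
cut_tree <- function(tree, k = 6) {
  n <- length(tree$order)
  if (k > n) stop("k = ", k, " exceeds the number of fish (", n, ")",
                  call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
}

#' Per-cluster chronology summaries and phenotype proportions
#'
#' Daily mean and SD ratio profiles per cluster, cluster sizes, and overall
#' phenotype proportions obtained by assigning each cluster the majority
#' phenotype of its supervised calls and summing cluster sizes per
#' phenotype (whole-percent, half-up rounding).
#'
#' @param chrons list of equal-length `sr_chronology` objects
#' @param labels integer cluster labels from [cut_tree()] (same order/names)
#' @param calls optional supervised calls data frame (`fish_id`,
#'   `phenotype`) for the phenotype mapping
#' @return list with `profiles` (data frame: cluster, age, mean, sd), `sizes`
#'   (named integer), and, when `calls` is given, `cluster_phenotype` and
#'   `phenotype_percent`
#' @export
summarize_clusters <- function(chrons, labels, calls = NULL) {
  ids <- vapply(chrons, attr, "", "fish_id")
  stopifnot(length(labels) == length(chrons))
  mat <- t(vapply(chrons, function(ch) ch$ratio, numeric(nrow(chrons[[1]]))))
  ages <- chrons[[1]]$age
  profs <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    m <- mat[labels == cl, , drop = FALSE]
    data.frame(cluster = cl, age = ages, mean = colMeans(m),
               sd = apply(m, 2, stats::sd))
  }))
  out <- list(profiles = profs, sizes = table(labels))
  if (!is.null(calls)) {
    phen <- calls$phenotype[match(ids, calls$fish_id)]
    maj <- vapply(sort(unique(labels)), function(cl) {
      names(which.max(table(phen[labels == cl])))
    }, "")
    names(maj) <- sort(unique(labels))
    counts <- tapply(tabulate(labels), maj[as.character(seq_along(maj))], sum)
    out$cluster_phenotype <- maj
    out$phenotype_percent <- phenotype_proportions(
      rep(names(counts), counts))
  }
  out
}
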