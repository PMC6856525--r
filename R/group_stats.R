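# Statistical validation of cluster structure: permutational MANOVA on the
# three life-history attributes and jackknifed quadratic discriminant
# reclassification.

round_half_up <- function(x) floor(x + 0.5)

#' Phenotype proportions in whole percent
#'
#' `100 * count / total`, rounded half-up to integers.
#'
#' @param phenotypes character vector (or factor) of phenotype labels
#' @return named integer percentages
#' @export
phenotype_proportions <- function(phenotypes) {
  if (length(phenotypes) == 0) stop("no phenotypes", call. = FALSE)
  tab <- table(phenotypes)
  stats::setNames(as.integer(round_half_up(100 * as.numeric(tab) /
                                             length(phenotypes))),
                  names(tab))
}

#' Permutational MANOVA on life-history attributes
#'
#' Attribute columns are z-score standardized (isotope ratios spread over
#' ~1e-3 while dispersal ages spread over tens of days, so unstandardized
#' Euclidean distances would be dominated by age alone), Euclidean distances
#' are formed, and the Anderson pseudo-F partition of the distance matrix is
#' tested by label permutation (`vegan::adonis2`), with the add-one
#' permutation p-value `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param x numeric matrix or data frame of attributes (complete cases only)
#' @param group group labels, one per row
#' @param n_perm number of label permutations (default 9999)
#' @param seed RNG seed for the permutations
#' @param standardize z-score the columns first (default TRUE)
#' @return list with `pseudo_F`, `p_value`, `df`, and the `adonis2` table
#' @export
permanova <- function(x, group, n_perm = 9999, seed = 1L,
                      standardize = TRUE) {
  x <- as.matrix(x)
  group <- as.factor(group)
  stopifnot(nrow(x) == length(group))
  if (any(!is.finite(x))) stop("attributes must be complete", call. = FALSE)
  if (any(table(group) < 2))
    stop("every group needs at least 2 members", call. = FALSE)
  if (standardize) x <- scale(x)
  d <- stats::dist(x)
  set.seed(seed)
  aov_tab <- vegan::adonis2(d ~ g, data = data.frame(g = group),
                            permutations = n_perm)
  list(pseudo_F = aov_tab$F[1], p_value = aov_tab$`Pr(>F)`[1],
       df = c(between = aov_tab$Df[1], within = aov_tab$Df[2]),
       table = aov_tab)
}

#' Jackknifed quadratic discriminant reclassification
#'
#' Leave-one-out QDA: each fish is assigned by a quadratic discriminant rule
#' (class-specific Gaussian means and unbiased covariances, priors
#' proportional to group size) refitted without that fish. The refit is
#' explicit, so the reported success rate is exactly the jackknife
#' reclassification rate. If a leave-one-out covariance is singular the rule
#' is refitted with a 1e-10 ridge on the covariance diagonal (with a
#' warning).
#'
#' @param x numeric matrix or data frame of attributes
#' @param group group labels
#' @return list with `confusion` (true x assigned), `overall_percent`
#'   (rounded to whole percent) and `overall` (unrounded)
#' @export
qda_jackknife <- function(x, group) {
  x <- as.matrix(x)
  group <- factor(group)
  stopifnot(nrow(x) == length(group))
  if (any(table(group) <= ncol(x) + 1))
    stop("each group needs more members than attributes + 1", call. = FALSE)
  pred <- tryCatch(qda_loo_ridge(x, group, ridge = 0),
                   error = function(e) {
                     warning("QDA covariance singular; refitting with 1e-10 ridge")
                     qda_loo_ridge(x, group, ridge = 1e-10)
                   })
  confusion <- table(true = group, assigned = pred)
  overall <- 100 * mean(pred == group)
  list(confusion = confusion,
       overall_percent = as.integer(round_half_up(overall)),
       overall = overall)
}

# explicit leave-one-out QDA with a diagonal ridge; also the shape of the
# naive reference rule used in the tests
qda_loo_ridge <- function(x, group, ridge = 0) {
  n <- nrow(x)
  lev <- levels(group)
  pred <- character(n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    gi <- group[-i]
    scores <- vapply(lev, function(g) {
      xg <- xi[gi == g, , drop = FALSE]
      mu <- colMeans(xg)
      S <- stats::cov(xg) + diag(ridge, ncol(x))
      ld <- determinant(S, logarithm = TRUE)$modulus
      z <- x[i, ] - mu
      -0.5 * ld - 0.5 * drop(z %*% solve(S, z)) + log(nrow(xg) / (n - 1))
    }, 0)
    pred[i] <- lev[which.max(scores)]
  }
  factor(pred, levels = lev)
}
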