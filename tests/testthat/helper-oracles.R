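# Independent reference implementations used only to cross-check package
# results. Deliberately naive: plain loops, textbook formulas.

# single mean-shift changepoint by direct RSS minimization with mean()/sum()
oracle_changepoint <- function(x, min_segment = 10) {
  n <- length(x)
  best_tau <- NA
  best_rss <- Inf
  for (tau in min_segment:(n - min_segment)) {
    a <- x[1:tau]
    b <- x[(tau + 1):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_tau <- tau
    }
  }
  rss0 <- sum((x - mean(x))^2)
  list(tau = best_tau, stat = n * log(rss0 / max(best_rss, 1e-300)))
}

# greedy Ward agglomeration straight from coordinates: at each step merge
# the pair of clusters whose fusion least increases total within-cluster SS;
# ties broken by lowest pair index. Returns the member partition after each
# merge.
oracle_ward_partitions <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- X[clusters[[i]], , drop = FALSE]
        b <- X[clusters[[j]], , drop = FALSE]
        dss <- sum((rbind(a, b) - rep(colMeans(rbind(a, b)),
                                      each = nrow(a) + nrow(b)))^2) -
          sum((a - rep(colMeans(a), each = nrow(a)))^2) -
          sum((b - rep(colMeans(b), each = nrow(b)))^2)
        if (dss < best_d - 1e-12) {
          best_d <- dss
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(partitions) + 1]] <-
      canonical_partition(clusters, nrow(X))
  }
  partitions
}

# label each observation by the smallest member index of its cluster
canonical_partition <- function(clusters, n) {
  lab <- integer(n)
  for (cl in clusters) lab[cl] <- min(cl)
  lab
}

# partitions after each merge of an hclust tree, same canonical labelling
hclust_partitions <- function(tree) {
  n <- length(tree$order)
  members <- lapply(seq_len(n), identity)  # leaves by negative index
  nodes <- list()
  partitions <- list()
  for (s in seq_len(nrow(tree$merge))) {
    pick <- function(v) if (v < 0) members[[-v]] else nodes[[v]]
    nodes[[s]] <- sort(c(pick(tree$merge[s, 1]), pick(tree$merge[s, 2])))
    active <- setdiff(seq_len(n), unlist(nodes[seq_len(s)]))
    live_nodes <- Filter(function(i) {
      !any(vapply(seq_len(s), function(j)
        j != i && all(nodes[[i]] %in% nodes[[j]]), TRUE))
    }, seq_len(s))
    clusters <- c(lapply(active, identity), nodes[live_nodes])
    partitions[[s]] <- canonical_partition(clusters, n)
  }
  partitions
}

# Anderson's PERMANOVA pseudo-F from the sum-of-squares partition
oracle_permanova_F <- function(X, group, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) X <- scale(X)
  d2 <- as.matrix(stats::dist(X))^2
  n <- nrow(X)
  g <- length(unique(group))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(group)) {
    idx <- which(group == lev)
    dd <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dd[upper.tri(dd)]) / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# naive leave-one-out QDA: refit Gaussian means/covariances without fish i,
# assign by log density + log prior (priors proportional to group size)
oracle_qda_loo <- function(X, group) {
  X <- as.matrix(X)
  group <- factor(group)
  n <- nrow(X)
  out <- character(n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_g <- group[-i]
    best <- -Inf
    for (lev in levels(group)) {
      xg <- tr_x[tr_g == lev, , drop = FALSE]
      mu <- colMeans(xg)
      S <- stats::cov(xg)
      z <- X[i, ] - mu
      score <- -0.5 * log(det(S)) -
        0.5 * drop(t(z) %*% solve(S) %*% z) + log(nrow(xg) / (n - 1))
      if (score > best) {
        best <- score
        out[i] <- lev
      }
    }
  }
  factor(out, levels = levels(group))
}

# brute-force moving-window outlier flags, recomputed independently
oracle_outlier_flags <- function(x, window = 40, k = 2) {
  n <- length(x)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - window %/% 2)
    hi <- min(n, i + window - window %/% 2 - 1)
    w <- x[lo:hi]
    flagged[i] <- abs(x[i] - mean(w)) > k * stats::sd(w)
  }
  flagged
}

# quick chronology wrapper for toy series (ages 0..length-1)
toy_chron <- function(ratio, fish_id = "toy") {
  sr_chronology(data.frame(age = seq_along(ratio) - 1, ratio = ratio,
                           salinity = NA_real_), fish_id = fish_id)
}

# default calibrated mixing model, shared across tests
test_mixing <- calibrate_freshwater_endmember(mixing_params())

# six cleanly separated life-history types (FWR, BWR, four SA dispersal-age
# sub-types with distinct adult salinities), rendered as daily chronologies
# with light jitter and measurement noise
make_six_type_cohort <- function(n = 120, seed = 1) {
  set.seed(seed)
  types <- data.frame(
    name = c("FWR", "BWR", "SA1", "SA2", "SA3", "SA4"),
    natal = c(0.1, 4, 0.1, 0.1, 0.1, 0.1),
    adult = c(0.1, 4, 1.5, 2.5, 3.5, 3.5),  # SA3/SA4 differ only in timing
    tau = c(NA, NA, 113, 93, 72, 51))
  p <- cohort_params(salinity_jitter_sd = 0.005, transition_width_days = 5)
  truth <- rep(types$name, length.out = n)
  chrons <- lapply(seq_len(n), function(i) {
    ty <- types[match(truth[i], types$name), ]
    phen <- if (ty$name == "FWR") "FWR" else if (ty$name == "BWR") "BWR"
    else "SA"
    tau <- if (phen == "SA") round(rnorm(1, ty$tau, 2)) else NA
    tc <- simulate_true_chronology(phen, 200, ty$natal, ty$adult, tau,
                                   params = p, mixing = test_mixing)
    sr_chronology(data.frame(age = 0:200,
                             ratio = tc$ratio + rnorm(201, 0, 1e-4)),
                  fish_id = sprintf("S%03d", i))
  })
  list(chrons = chrons, truth = truth)
}

# a noise-free toy ablation run with given blank/ablation intensity matrices
make_toy_run <- function(n_blank = 12, n_abl = 60, i88 = 1e6,
                         ratio = 0.707, i85 = 0, blank = 0,
                         bias_86_88 = 0.1194) {
  n <- n_blank + n_abl
  t <- seq(0.25, by = 0.25, length.out = n)
  seg <- rep(c("blank", "ablation"), c(n_blank, n_abl))
  abl <- seg == "ablation"
  d <- data.frame(fish_id = "toy", time_s = t,
                  i84 = ifelse(abl, i88 * bias_86_88 * 0.0565, 0) + blank,
                  i85 = ifelse(abl, i85, 0) + blank,
                  i86 = ifelse(abl, i88 * bias_86_88, 0) + blank,
                  i87 = ifelse(abl, i88 * bias_86_88 * ratio, 0) + blank,
                  i88 = ifelse(abl, i88, 0) + blank,
                  segment = seg, stringsAsFactors = FALSE)
  ablation_run(d, core_offset_um = 0)
}
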