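test_that("level-1 Haar coefficients follow the orthonormal convention", {
  expect_equal(haar_level1(c(1, 1, 1, 1)), c(sqrt(2), sqrt(2)))
  expect_equal(haar_level1(c(2, 4, 6, 8)), c(6, 14) / sqrt(2))
  expect_error(haar_level1(1:5), "even")

  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(170)
    a <- haar_level1(x)
    d <- (x[seq(1, 169, 2)] - x[seq(2, 170, 2)]) / sqrt(2)
    expect_lt(abs(sum(a^2) + sum(d^2) - sum(x^2)), 1e-10)  # Parseval
  }
})

test_that("feature distances are Euclidean and contract the raw distance", {
  ch_a <- toy_chron(rep(0.7060, 170), "a")
  ch_b <- toy_chron(rep(0.7080, 170), "b")
  ch_c <- toy_chron(rep(0.7060, 170), "c")  # same values as a
  feats <- dwt_features(list(ch_a, ch_b, ch_c))
  d <- as.matrix(pairwise_distances(feats))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], sqrt(170) * 0.0020, tolerance = 1e-9)

  set.seed(9)
  for (i in 1:20) {
    x <- matrix(rnorm(3 * 170), 3)
    f <- t(apply(x, 1, haar_level1))
    df <- as.matrix(dist(f))
    dx <- as.matrix(dist(x))
    expect_lte(df[1, 2], df[1, 3] + df[2, 3] + 1e-12)  # triangle
    expect_lte(df[1, 2], dx[1, 2] + 1e-12)             # contraction
  }

  expect_error(dwt_features(list(ch_a, toy_chron(rep(0.706, 100), "c"))),
               "same length")
})

test_that("Ward merges match the greedy minimal-variance oracle", {
  d1 <- dist(matrix(c(0, 1, 10), ncol = 1))
  tree <- ward_cluster(d1)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # {0,1} merge first

  expect_equal(nrow(ward_cluster(dist(matrix(c(0, 3), ncol = 1)))$merge), 1)

  set.seed(10)
  for (s in 1:30) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 2), n)
    tree <- ward_cluster(dist(X))
    expect_identical(hclust_partitions(tree), oracle_ward_partitions(X))
    expect_true(all(diff(tree$height) >= -1e-10))
  }
})

test_that("tree cutting renumbers by size and is permutation invariant", {
  set.seed(12)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(6, 5, 0.1), 3),
             matrix(rnorm(10, 10, 0.1), 5))
  rownames(X) <- sprintf("f%02d", 1:18)
  lab <- cut_tree(ward_cluster(dist(X)), k = 3)
  expect_equal(as.integer(table(lab)), c(10, 5, 3))  # descending sizes
  expect_equal(unname(lab[1:10]), rep(1L, 10))

  perm <- sample(18)
  lab_p <- cut_tree(ward_cluster(dist(X[perm, ])), k = 3)
  expect_equal(unname(lab_p[rownames(X)]), unname(lab))

  expect_equal(length(unique(cut_tree(ward_cluster(dist(X)), k = 18))), 18)
  expect_equal(unique(cut_tree(ward_cluster(dist(X)), k = 1)), 1L)
  expect_error(cut_tree(ward_cluster(dist(X)), k = 19), "exceeds")
})

test_that("cluster summaries report profiles, sizes and proportions", {
  chrons <- c(lapply(1:3, function(i) toy_chron(rep(0.7060, 170),
                                                paste0("f", i))),
              lapply(4, function(i) toy_chron(rep(0.7082, 170),
                                              paste0("f", i))))
  labels <- c(1L, 1L, 1L, 2L)
  calls <- data.frame(fish_id = paste0("f", 1:4),
                      phenotype = c("FWR", "FWR", "FWR", "BWR"))
  sm <- summarize_clusters(chrons, labels, calls)
  expect_equal(as.vector(sm$sizes), c(3L, 1L))
  expect_true(all(sm$profiles$sd[sm$profiles$cluster == 1] == 0))
  expect_equal(unname(sm$phenotype_percent[c("FWR", "BWR")]), c(75L, 25L))
  expect_equal(unname(sm$cluster_phenotype), c("FWR", "BWR"))
})

test_that("a strongly separated six-type cohort is recovered at k = 6", {
  skip_if_not_installed("mclust")
  co <- make_six_type_cohort(n = 120, seed = 31)
  trimmed <- lapply(co$chrons, trim_chronology, max_age = 170)
  labels <- cut_tree(ward_cluster(pairwise_distances(dwt_features(trimmed))),
                     k = 6)
  ari <- mclust::adjustedRandIndex(labels, co$truth)
  expect_gt(ari, 0.9)
})
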