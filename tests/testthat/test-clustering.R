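# planted trajectory data: k well-separated shape templates
planted_scores <- function(n_per = 5, k = 6, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * 3), k) * sep
  scores <- centers[rep(1:k, each = n_per), ] + matrix(rnorm(n_per * k * 3, 0, sd),
                                                       n_per * k)
  rownames(scores) <- paste0("c", seq_len(nrow(scores)))
  list(scores = scores, labels = rep(1:k, each = n_per))
}

test_that("preprocessing normalizes rows then demeans columns", {
  set.seed(2)
  m <- matrix(runif(60, 0.1, 0.5), 5, 12)
  rownames(m) <- paste0("c", 1:5)
  out <- preprocess_trajectories(m)
  z <- out$processed
  expect_lt(max(abs(colMeans(z))), 1e-12)
  # row-normalization step before demeaning: reconstruct it
  zn <- (m - rowMeans(m)) / apply(m, 1, function(x) sqrt(mean((x - mean(x))^2)))
  expect_lt(max(abs(rowMeans(zn))), 1e-12)
  expect_equal(apply(zn, 1, function(x) mean(x^2)), rep(1, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(z, sweep(zn, 2, colMeans(zn)), tolerance = 1e-12)
})

test_that("preprocessing is invariant to level and positive scale", {
  set.seed(3)
  m <- matrix(runif(48, 0.1, 0.4), 4, 12)
  m2 <- m
  m2[2, ] <- 0.2 + 3 * m[1, ]   # same shape as row 1, shifted and scaled
  out <- preprocess_trajectories(m2)
  expect_equal(out$processed[1, ], out$processed[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a 3x3 hand example matches step-by-step arithmetic", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(5, 5, 8))
  # row 1: mean 2, pop sd sqrt(2/3); row 2: mean 4, sd 2*sqrt(2/3);
  # row 3: mean 6, sd sqrt(2)
  s23 <- sqrt(2 / 3)
  zn <- rbind(c(-1, 0, 1) / s23, c(-2, 0, 2) / (2 * s23),
              c(-1, -1, 2) / sqrt(2))
  expected <- sweep(zn, 2, colMeans(zn))
  expect_equal(unname(preprocess_trajectories(m)$processed), expected,
               tolerance = 1e-12)
})

test_that("zero-variance trajectories are excluded with a warning", {
  m <- rbind(c(1, 2, 3), c(2, 2, 2))
  rownames(m) <- c("a", "b")
  expect_warning(out <- preprocess_trajectories(m), "zero-variance")
  expect_equal(rownames(out$processed), "a")
  expect_equal(out$excluded, "b")
})

test_that("PCA explains rank-3 data exactly and is sign-deterministic", {
  set.seed(5)
  base <- matrix(rnorm(3 * 12), 3, 12)
  w <- matrix(rnorm(20 * 3), 20, 3)
  m <- w %*% base
  m <- sweep(m, 2, colMeans(m))
  out <- pca_reduce(m, 3)
  expect_gt(sum(out$explained[1:3]), 1 - 1e-9)
  # reconstruction from scores and loadings
  rec <- out$scores %*% t(out$loadings)
  expect_equal(rec, m, tolerance = 1e-8, ignore_attr = TRUE)
  # fixed sign convention: largest-magnitude loading positive
  for (i in 1:3) {
    expect_gt(out$loadings[which.max(abs(out$loadings[, i])), i], 0)
  }
  expect_identical(out$scores, pca_reduce(m, 3)$scores)
})

test_that("k-means recovers planted blobs and respects best-of-restarts", {
  pl <- planted_scores(sep = 10, sd = 1)
  al <- kmeans_allocate(pl$scores, k = 6, n_starts = 50, seed = 2)
  ari <- mclust::adjustedRandIndex(al$cluster, pl$labels)
  expect_gte(ari, 0.99)
  expect_true(all(al$inertia <= al$restart_inertia + 1e-9))
  al2 <- kmeans_allocate(pl$scores, k = 6, n_starts = 50, seed = 2)
  expect_identical(al$cluster, al2$cluster)
  expect_error(kmeans_allocate(pl$scores[1:4, ], k = 6), "at least k")
})

test_that("cluster membership is invariant to level and scale of raw series", {
  set.seed(11)
  years <- 20
  shapes <- rbind(seq(0, 1, length.out = years),
                  seq(1, 0, length.out = years),
                  sin(seq(0, pi, length.out = years)))
  m <- shapes[rep(1:3, each = 6), ] + matrix(rnorm(18 * years, 0, 0.02), 18)
  rownames(m) <- paste0("c", 1:18)
  m2 <- m
  m2[1, ] <- 10 + 5 * m[1, ]
  p1 <- preprocess_trajectories(m)$processed
  p2 <- preprocess_trajectories(m2)$processed
  expect_equal(p1[1, ], p2[1, ], tolerance = 1e-9)
  a1 <- kmeans_allocate(pca_reduce(p1)$scores, k = 3, n_starts = 20, seed = 1)
  a2 <- kmeans_allocate(pca_reduce(p2)$scores, k = 3, n_starts = 20, seed = 1)
  expect_equal(mclust::adjustedRandIndex(a1$cluster, a2$cluster), 1)
})

test_that("Jaccard stability is high on separable data", {
  pl <- planted_scores(sep = 12, sd = 0.8, seed = 7)
  rep <- jaccard_stability(pl$scores, k = 6, proportions = 0.9,
                           n_subsamples = 50, seed = 3, n_starts = 20)
  expect_s3_class(rep, "data.frame")
  expect_true(all(rep$mean_jaccard >= 0.9))
  expect_true(all(rep$mean_jaccard <= 1))
})

test_that("identical partitions give Jaccard index one", {
  pl <- planted_scores(sep = 50, sd = 0.01, seed = 9)
  rep <- jaccard_stability(pl$scores, k = 6, proportions = 1.0,
                           n_subsamples = 3, seed = 5, n_starts = 10)
  expect_true(all(rep$mean_jaccard == 1))
})

test_that("the k sweep reports inertia and silhouette over the range", {
  pl <- planted_scores(n_per = 4, sep = 8, seed = 13)
  sw <- kmeans_k_sweep(pl$scores, k_range = 3:8, n_starts = 10, seed = 1)
  expect_equal(sw$k, 3:8)
  expect_true(all(diff(sw$inertia) <= 1e-9))  # inertia non-increasing in k
  expect_true(which.max(sw$mean_silhouette) == which(sw$k == 6))
})

test_that("typology labels annotate cluster mean trajectories", {
  years <- 30
  up <- cumsum(c(0, rep(0.5, years - 1)))        # steady increase
  accel <- 0.01 * (seq_len(years))^2             # accelerating
  decl <- c(seq(0, 5, length.out = 20), seq(5, 3, length.out = 10))
  m <- rbind(up, up + 0.2, accel, accel * 1.1, decl, decl + 0.1)
  rownames(m) <- paste0("c", 1:6)
  cl <- c(1, 1, 2, 2, 3, 3)
  lab <- bmitrend:::cluster_typology(m, cl)
  expect_equal(length(lab), 3)
  expect_true(lab[2] %in% c("accelerating increase", "steady increase"))
  expect_equal(lab[3], "recent decline")
})
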