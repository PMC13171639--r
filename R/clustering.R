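#' Preprocess national prevalence trajectories for clustering
#'
#' Each country's series is normalized to zero mean and unit variance
#' (population standard deviation, divisor n) so that clustering is driven by
#' trajectory shape rather than level or amplitude; then the annual mean
#' normalized prevalence across countries is subtracted from every column to
#' remove the overall temporal trend. Rows with zero variance cannot be shape-
#' normalized and are excluded with a warning.
#'
#' @param mat countries x years numeric matrix (rownames = countries).
#' @return list: `processed` matrix (possibly fewer rows), `excluded`
#'   (rownames of dropped zero-variance rows).
#' @export
preprocess_trajectories <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  sds <- apply(mat, 1, pop_sd)
  bad <- sds == 0
  excluded <- if (is.null(rownames(mat))) which(bad) else rownames(mat)[bad]
  if (any(bad)) {
    warning(sprintf("%d zero-variance trajectories excluded", sum(bad)))
    mat <- mat[!bad, , drop = FALSE]
    sds <- sds[!bad]
  }
  z <- (mat - rowMeans(mat)) / sds
  z <- sweep(z, 2, colMeans(z))
  list(processed = z, excluded = excluded)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Principal-component scores of processed trajectories
#'
#' Projects the processed country trajectories onto the leading right-singular
#' directions. The sign of each component is fixed by making its largest-
#' magnitude loading positive, so output is deterministic.
#'
#' @param processed output matrix of [preprocess_trajectories()].
#' @param n_components number of components (default 3).
#' @return list: `scores` (countries x n_components), `explained` (variance
#'   fractions, all components), `loadings` (years x n_components).
#' @export
pca_reduce <- function(processed, n_components = 3) {
  stopifnot(nrow(processed) > n_components)
  sv <- svd(processed)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  V <- sv$v[, k, drop = FALSE]
  for (i in k) {
    s <- sign(V[which.max(abs(V[, i])), i])
    if (s < 0) V[, i] <- -V[, i]
  }
  scores <- processed %*% V
  rownames(scores) <- rownames(processed)
  list(scores = scores, explained = ev, loadings = V)
}

#' Best-of-restarts k-means allocation
#'
#' Euclidean k-means on the component scores with `n_starts` random
#' initializations; the allocation with the minimum total within-cluster sum
#' of squares (inertia) is returned, together with each restart's inertia.
#' Clusters are annotated with a typology label derived from the mean raw
#' trajectory of their members when `raw` is supplied.
#'
#' @param scores countries x components matrix.
#' @param k number of clusters (default 6).
#' @param n_starts random restarts (default 50).
#' @param seed integer seed.
#' @param raw optional countries x years matrix of raw (unprocessed)
#'   trajectories for typology labelling.
#' @return list of class "cluster_allocation": `cluster` (named integer
#'   vector), `centers`, `inertia`, `restart_inertia`, `k`, `seed`,
#'   `typology` (per-cluster label or NULL).
#' @export
kmeans_allocate <- function(scores, k = 6, n_starts = 50, seed = 1L, raw = NULL) {
  if (nrow(scores) < k) stop("need at least k countries")
  if (nrow(unique(as.data.frame(scores))) < k)
    stop("fewer than k distinct score points; k unattainable")
  set.seed(seed)
  best <- NULL
  inertias <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    km <- suppressWarnings(stats::kmeans(scores, centers = k, nstart = 1,
                                         iter.max = 100, algorithm = "Lloyd"))
    inertias[s] <- km$tot.withinss
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  cl <- best$cluster
  names(cl) <- rownames(scores)
  typ <- if (!is.null(raw)) cluster_typology(raw, cl) else NULL
  structure(list(cluster = cl, centers = best$centers,
                 inertia = best$tot.withinss, restart_inertia = inertias,
                 k = k, seed = seed, typology = typ),
            class = "cluster_allocation")
}

# heuristic typology labels from cluster-mean trajectories: signs of the mean
# first difference early and late, and of the mean second difference
cluster_typology <- function(raw, cluster) {
  vapply(sort(unique(cluster)), function(cid) {
    m <- colMeans(raw[cluster == cid, , drop = FALSE])
    d <- diff(m)
    half <- length(d) %/% 2
    early <- mean(d[seq_len(half)]); late <- mean(d[(half + 1):length(d)])
    accel <- mean(diff(d))
    eps <- 0.1 * stats::sd(d) + 1e-12
    if (late > eps && accel > eps / 2) "accelerating increase"
    else if (late > eps && accel < -eps / 2) "decelerating increase"
    else if (late > eps) "steady increase"
    else if (late < -eps) "recent decline"
    else if (early > eps) "plateau"
    else "flat"
  }, "")
}

#' Jaccard stability of a clustering under subsampling
#'
#' For each subsample proportion, draws `n_subsamples` subsets of countries
#' without replacement, reclusters each subset, and records for every
#' reference cluster the Jaccard index |A n B| / |A u B| against the most
#' similar subsample cluster, with the reference cluster restricted to the
#' retained countries. Ties in "most similar" go to the larger intersection,
#' then the lower cluster id. Reported values are means over replicates.
#'
#' @param scores countries x components matrix.
#' @param k number of clusters.
#' @param proportions subsample proportions (default 0.5 to 0.9).
#' @param n_subsamples replicates per proportion (default 1000).
#' @param seed integer seed.
#' @param n_starts k-means restarts for reference and subsample clusterings.
#' @return data frame (proportion, cluster, mean_jaccard, n_replicates) of
#'   class "stability_report", with the reference allocation as attribute.
#' @export
jaccard_stability <- function(scores, k = 6, proportions = seq(0.5, 0.9, 0.1),
                              n_subsamples = 1000, seed = 1L, n_starts = 50) {
  nC <- nrow(scores)
  if (floor(min(proportions) * nC) < k)
    stop("smallest subsample would have fewer countries than k")
  ref <- kmeans_allocate(scores, k, n_starts, seed)
  ref_sets <- split(seq_len(nC), ref$cluster)
  out <- list()
  set.seed(derive_seed(seed, 999L))
  for (p in proportions) {
    nsub <- floor(p * nC)
    acc <- matrix(NA_real_, n_subsamples, k)
    for (r in seq_len(n_subsamples)) {
      idx <- sort(sample.int(nC, nsub))
      sub <- kmeans_allocate(scores[idx, , drop = FALSE], k,
                             n_starts = max(10, n_starts %/% 5),
                             seed = derive_seed(seed, r + 131L))
      sub_sets <- split(idx[seq_len(nsub)], sub$cluster)
      for (ci in seq_len(k)) {
        A <- intersect(ref_sets[[ci]], idx)
        if (!length(A)) { acc[r, ci] <- NA_real_; next }
        best <- 0; best_inter <- -1
        for (si in seq_along(sub_sets)) {
          Bset <- sub_sets[[si]]
          inter <- length(intersect(A, Bset))
          jac <- inter / length(union(A, Bset))
          if (jac > best || (jac == best && inter > best_inter)) {
            best <- jac; best_inter <- inter
          }
        }
        acc[r, ci] <- best
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      proportion = p, cluster = seq_len(k),
      mean_jaccard = colMeans(acc, na.rm = TRUE),
      n_replicates = colSums(!is.na(acc)))
  }
  rep <- do.call(rbind, out)
  attr(rep, "reference") <- ref
  class(rep) <- c("stability_report", "data.frame")
  rep
}

#' Inertia and silhouette sweep over k
#'
#' Companion heuristics for choosing k: total within-cluster sum of squares
#' (elbow) and mean silhouette width for each k in `k_range`.
#'
#' @param scores countries x components matrix.
#' @param k_range candidate k values (default 3..20).
#' @param n_starts restarts per k.
#' @param seed integer seed.
#' @return data frame (k, inertia, mean_silhouette).
#' @export
kmeans_k_sweep <- function(scores, k_range = 3:20, n_starts = 50, seed = 1L) {
  d <- as.matrix(stats::dist(scores))
  out <- lapply(k_range, function(k) {
    al <- kmeans_allocate(scores, k, n_starts, seed)
    data.frame(k = k, inertia = al$inertia,
               mean_silhouette = mean_silhouette(d, al$cluster))
  })
  do.call(rbind, out)
}

mean_silhouette <- function(dmat, cluster) {
  n <- length(cluster)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) sum(dmat[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(cluster), cluster[i]), function(cl)
      mean(dmat[i, cluster == cl]), 0.0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}
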