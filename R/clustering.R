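# Clustering of biomolecules by their free-energy fingerprints, cluster
# count diagnostics (PCA spectrum, k-means inertia elbow), and selection of
# one representative probe molecule per cluster.

#' Distance matrix between molecule fingerprints
#'
#' Euclidean distance between the rows of the free-energy matrix, i.e.
#' between the molecules' binding profiles across all materials. The
#' `"rms"` normalization divides by `sqrt(n_materials)` (root-mean-squared
#' distance); it is a global rescaling that changes dendrogram heights but
#' no merge order or assignment.
#'
#' @param m an [fe_matrix()] or a numeric matrix with rownames.
#' @param normalize `"euclidean"` (default) or `"rms"`.
#' @return a [stats::dist] object with labels.
#' @export
molecule_distance_matrix <- function(m,
                                     normalize = c("euclidean", "rms")) {
  normalize <- match.arg(normalize)
  x <- if (inherits(m, "fe_matrix")) m$values else m
  if (any(!is.finite(x))) stop("matrix contains missing values",
                               call. = FALSE)
  d <- stats::dist(x, method = "euclidean")
  if (normalize == "rms") d <- d / sqrt(ncol(x))
  d
}

#' Ward agglomerative clustering
#'
#' Agglomerative clustering under the Ward criterion: at each step the pair
#' of clusters whose merge minimally increases the total within-cluster sum
#' of squares is joined. Heights are on the scale of the input distances
#' (for two singletons at Euclidean distance `d` the merge height is `d`)
#' and are monotone non-decreasing along the merge sequence.
#'
#' @param d a [stats::dist] of Euclidean (or rms-scaled) distances.
#' @return a [stats::hclust] tree.
#' @export
ward_linkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 2L) stop("need at least 2 items", call. = FALSE)
  stats::hclust(d, method = "ward.D2")
}

#' Cut a linkage tree into k clusters
#'
#' @param tree a [stats::hclust] tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels (1..k).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k out of range 1..", n, call. = FALSE)
  stats::cutree(tree, k = k)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# next center sampled with probability proportional to squared distance to
# the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[idx[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, colSums((t(x) - x[idx[j + 1L], ])^2))
  }
  x[idx, , drop = FALSE]
}

.lloyd_from <- function(x, centers, iter.max = 300L) {
  km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter.max,
                                       algorithm = "Lloyd"))
  km
}

#' K-means partition of molecules
#'
#' Lloyd iterations from k-means++ seeding, best of `n_restarts` by
#' inertia (total within-cluster sum of squared Euclidean distances to the
#' assigned centroid).
#'
#' @param m an [fe_matrix()] or numeric matrix with rownames (items in
#'   rows).
#' @param k number of clusters.
#' @param n_restarts independent seedings (default 10).
#' @param seed integer seed.
#' @param iter.max Lloyd iteration cap (default 300).
#' @return list with `partition` (named integer vector), `inertia`,
#'   `centers`.
#' @export
kmeans_partition <- function(m, k, n_restarts = 10L, seed = 1L,
                             iter.max = 300L) {
  x <- if (inherits(m, "fe_matrix")) m$values else m
  if (k > nrow(x)) stop("k exceeds the number of items", call. = FALSE)
  if (k == nrow(x)) {
    part <- stats::setNames(seq_len(nrow(x)), rownames(x))
    return(list(partition = part, inertia = 0, centers = x))
  }
  withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- .lloyd_from(x, .kmeanspp_centers(x, k), iter.max)
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(partition = stats::setNames(best$cluster, rownames(x)),
         inertia = best$tot.withinss, centers = best$centers)
  })
}

#' Inertia elbow curve over candidate cluster counts
#'
#' Runs [kmeans_partition()] for each `k` and additionally warm-starts each
#' `k` from the previous solution's centers plus the point worst fit by
#' them, which makes the reported curve non-increasing in `k`. The
#' suggested elbow is the `k` of maximum discrete curvature.
#'
#' @inheritParams kmeans_partition
#' @param ks candidate cluster counts (default 1:8).
#' @return list with `k`, `inertia`, `suggested_k`.
#' @export
inertia_curve <- function(m, ks = 1:8, n_restarts = 10L, seed = 1L) {
  x <- if (inherits(m, "fe_matrix")) m$values else m
  ks <- sort(unique(as.integer(ks)))
  if (max(ks) > nrow(x)) stop("k exceeds the number of items",
                              call. = FALSE)
  inert <- numeric(length(ks))
  prev_centers <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    res <- kmeans_partition(x, k, n_restarts, seed = seed + k)
    if (!is.null(prev_centers) && k == nrow(prev_centers) + 1L &&
        k < nrow(x)) {
      # warm start: previous centers plus the point farthest from them
      d2 <- apply(x, 1L, function(r)
        min(colSums((t(prev_centers) - r)^2)))
      cand <- unique(rbind(prev_centers, x[which.max(d2), ]))
      if (nrow(cand) == k) {
        km <- .lloyd_from(x, cand)
        if (km$tot.withinss < res$inertia)
          res <- list(partition = stats::setNames(km$cluster, rownames(x)),
                      inertia = km$tot.withinss, centers = km$centers)
      }
    }
    inert[i] <- res$inertia
    prev_centers <- res$centers
  }
  sugg <- if (length(ks) >= 3L) {
    curv <- diff(diff(inert))          # second difference, interior ks
    ks[which.max(curv) + 1L]
  } else ks[1L]
  list(k = ks, inertia = inert, suggested_k = sugg)
}

# Minka's Laplace-evidence approximation for the number of principal
# components, evaluated on the covariance spectrum; argmax over rank
# 1..p-1 (rank 0 excluded).
.minka_loglik <- function(spectrum, rank, n) {
  p <- length(spectrum)
  eps <- 1e-15
  if (spectrum[rank] < eps) return(-Inf)
  pu <- -rank * log(2)
  for (i in seq_len(rank))
    pu <- pu + lgamma((p - i + 1) / 2) - log(pi) * (p - i + 1) / 2
  pl <- -sum(log(spectrum[seq_len(rank)])) * n / 2
  v <- max(eps, sum(spectrum[-seq_len(rank)]) / (p - rank))
  pv <- -log(v) * n * (p - rank) / 2
  m <- p * rank - rank * (rank + 1) / 2
  pp <- log(2 * pi) * (m + rank) / 2
  spec_ <- spectrum
  spec_[(rank + 1L):p] <- v
  pa <- 0
  for (i in seq_len(rank))
    for (j in seq.int(i + 1L, p))
      pa <- pa + log((spectrum[i] - spectrum[j]) *
                       (1 / spec_[j] - 1 / spec_[i])) + log(n)
  pu + pl + pv + pp - pa / 2 - rank * log(n) / 2
}

.minka_mle <- function(spectrum, n) {
  p <- length(spectrum)
  if (p < 2L) return(p)
  ll <- vapply(seq_len(p - 1L), function(r) .minka_loglik(spectrum, r, n),
               0)
  if (all(!is.finite(ll))) {
    # degenerate spectrum: ratio-threshold fallback
    tot <- sum(spectrum)
    if (tot <= 0) return(0L)
    return(sum(spectrum / tot > 0.01))
  }
  which.max(ll)
}

#' PCA variance spectrum of the fingerprint matrix
#'
#' Singular value decomposition of the column-centered matrix; returns the
#' explained-variance ratio per principal component and an estimate of the
#' number of meaningful components by Minka's MLE (with a ratio-threshold
#' fallback for degenerate spectra).
#'
#' @param m an [fe_matrix()] or numeric matrix (observations in rows).
#' @return list with `explained_variance_ratio` (non-increasing, sums to
#'   <= 1) and `n_components_estimate`.
#' @export
pca_variance <- function(m) {
  x <- if (inherits(m, "fe_matrix")) m$values else m
  if (nrow(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)$d
  ev <- sv^2 / (nrow(x) - 1)            # covariance spectrum
  tot <- sum(ev)
  if (tot <= .Machine$double.eps * nrow(x)) {
    return(list(explained_variance_ratio = rep(0, length(ev)),
                n_components_estimate = 0L))
  }
  k <- min(dim(x))
  spectrum <- ev[seq_len(k)]
  list(explained_variance_ratio = ev / tot,
       n_components_estimate = as.integer(.minka_mle(spectrum, nrow(x))))
}

#' Representative molecule of each cluster
#'
#' For every cluster, the centroid is the arithmetic mean of the member
#' fingerprints and the representative is the member with minimal Euclidean
#' distance to that centroid; ties are broken by input order.
#'
#' @param m an [fe_matrix()] or numeric matrix with rownames.
#' @param partition named integer vector of cluster labels covering the
#'   rows of `m` (e.g. from [cut_tree()]).
#' @return named character vector: one molecule id per cluster label, in
#'   cluster-label order. The `distances` attribute carries each
#'   representative's distance to its centroid.
#' @export
select_representatives <- function(m, partition) {
  x <- if (inherits(m, "fe_matrix")) m$values else m
  ids <- rownames(x)
  if (!setequal(names(partition), ids))
    stop("partition must label exactly the molecules of the matrix",
         call. = FALSE)
  partition <- partition[ids]
  labs <- sort(unique(partition))
  reps <- character(length(labs))
  dists <- numeric(length(labs))
  for (i in seq_along(labs)) {
    members <- ids[partition == labs[i]]
    if (!length(members)) stop("empty cluster ", labs[i], call. = FALSE)
    centroid <- colMeans(x[members, , drop = FALSE])
    d <- sqrt(colSums((t(x[members, , drop = FALSE]) - centroid)^2))
    j <- which.min(d)                  # first minimum = input order
    reps[i] <- members[j]
    dists[i] <- d[j]
  }
  structure(stats::setNames(reps, labs), distances = dists)
}

#' Export a linkage tree as a Newick string
#'
#' @param tree a [stats::hclust] tree with labels.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to file.
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) ape::write.tree(phy)
  else invisible(ape::write.tree(phy, file = path))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement in `[-1, 1]`; 1 means identical up to
#' relabeling.
#'
#' @param a,b partitions as vectors of cluster labels over the same items
#'   (matched by names when both are named, else by position).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions label different item sets", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  mclust::adjustedRandIndex(as.vector(a), as.vector(b))
}
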