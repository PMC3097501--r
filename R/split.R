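#' Seeded Lloyd k-means
#'
#' Plain Lloyd iteration with deterministic seeding: initial centroids are
#' `k` distinct points sampled uniformly under `seed`, points are reassigned
#' to the nearest centroid (ties broken by lowest cluster index), and
#' centroids are recomputed until a fixed point or `max_iter`.  A cluster
#' left empty is re-seeded from the point currently farthest from its own
#' centroid, which strictly decreases the within-cluster sum of squares; if
#' the data cannot support `k` distinct centroids (all-identical points) the
#' empty cluster is allowed with a warning.
#'
#' Used for rational training/test division; `stats::kmeans` is the obvious
#' alternative but does not expose the seeded-deterministic, empty-cluster
#' and iteration-trajectory behaviour needed here.
#'
#' @param points Numeric matrix (rows = observations).
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param seed Integer RNG seed for initialization.
#' @param max_iter Iteration cap (default 100).
#' @return List with `centroids` (k x K), `cluster` (assignment per row),
#'   `wcss` (final within-cluster sum of squares), `trajectory` (WCSS after
#'   each Lloyd iteration, non-increasing), `iterations`, `converged`, `seed`.
#' @export
lloyd_kmeans <- function(points, k, seed = 1L, max_iter = 100L) {
  m <- as_descriptor_matrix(points)
  n <- nrow(m)
  if (k < 1L || k > n) stop_("k must be in [1, %d], got %s", n, format(k))
  with_seed(seed, {
    centroids <- m[sample.int(n, k), , drop = FALSE]
    cluster <- integer(n)
    trajectory <- numeric(0L)
    converged <- FALSE
    warned_empty <- FALSE
    iter <- 0L
    dist2 <- function(cent) {
      # n x k squared Euclidean distances
      outer(rowSums(m^2), rep(1, nrow(cent))) - 2 * m %*% t(cent) +
        outer(rep(1, n), rowSums(cent^2))
    }
    while (iter < max_iter) {
      iter <- iter + 1L
      d2 <- dist2(centroids)
      new_cluster <- apply(d2, 1L, which.min)  # first min -> lowest index
      # revive empty clusters from the farthest point
      for (j in which(tabulate(new_cluster, k) == 0L)) {
        cur <- d2[cbind(seq_len(n), new_cluster)]
        far <- which.max(cur)
        if (cur[far] <= .Machine$double.eps) {
          if (!warned_empty) {
            warn_("cluster %d left empty: points cannot support k=%d distinct clusters",
                  j, k)
            warned_empty <- TRUE
          }
          next
        }
        centroids[j, ] <- m[far, ]
        new_cluster[far] <- j
        d2 <- dist2(centroids)
        new_cluster <- apply(d2, 1L, which.min)
        new_cluster[far] <- j
      }
      for (j in seq_len(k)) {
        inj <- new_cluster == j
        if (any(inj)) centroids[j, ] <- colMeans(m[inj, , drop = FALSE])
      }
      wcss <- sum((m - centroids[new_cluster, , drop = FALSE])^2)
      trajectory <- c(trajectory, wcss)
      if (iter > 1L && identical(new_cluster, cluster)) {
        converged <- TRUE
        cluster <- new_cluster
        break
      }
      cluster <- new_cluster
    }
    list(centroids = centroids, cluster = cluster,
         wcss = trajectory[length(trajectory)], trajectory = trajectory,
         iterations = iter, converged = converged, seed = seed)
  })
}

#' Cluster-guided training/test split
#'
#' Divides compounds into a training and an external test set so that the
#' test set covers the whole standardized descriptor space: the compounds
#' are clustered by [lloyd_kmeans()] into `k = round(test_fraction * N)`
#' clusters and the compound nearest each cluster centroid is assigned to
#' the test set (ties broken by lowest compound index); everything else
#' trains.  With the conventional quarter held out, a 33-compound dataset
#' yields exactly 8 test compounds.
#'
#' @param table Descriptor data; standardized internally (z-scoring is
#'   idempotent, so pre-standardized input is fine).
#' @param test_fraction Fraction of compounds held out, in (0, 0.5);
#'   default 0.25.
#' @param seed Integer seed controlling the clustering.
#' @return A data.frame of class `split_assignment` with columns `compound`,
#'   `cluster`, `role` (`"train"`/`"test"`), and attributes `seed`, `k`.
#' @export
kmeans_split <- function(table, test_fraction = 0.25, seed = 1L) {
  m <- as_descriptor_matrix(table)
  n <- nrow(m)
  if (n < 8L) stop_("too few compounds to split (n=%d, need >= 8)", n)
  if (test_fraction <= 0 || test_fraction >= 0.5) {
    stop_("test_fraction must be in (0, 0.5)")
  }
  keep <- apply(m, 2L, stats::sd) > 0
  z <- descriptor_values(standardize(m[, keep, drop = FALSE])$table)
  k <- max(1L, round(test_fraction * n))
  km <- lloyd_kmeans(z, k, seed = seed)
  test_idx <- integer(0L)
  for (j in seq_len(k)) {
    members <- which(km$cluster == j)
    if (!length(members)) next
    d2 <- rowSums((z[members, , drop = FALSE] -
                     matrix(km$centroids[j, ], length(members),
                            ncol(z), byrow = TRUE))^2)
    test_idx <- c(test_idx, members[which.min(d2)])
  }
  role <- rep("train", n)
  role[test_idx] <- "test"
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(compound = ids, cluster = km$cluster, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "k") <- k
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment: %d train / %d test (k=%d clusters, seed=%s)>\n",
              sum(x$role == "train"), sum(x$role == "test"),
              attr(x, "k"), format(attr(x, "seed"))))
  invisible(x)
}
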