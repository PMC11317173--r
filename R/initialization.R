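#' K-means partition of the VAF vectors
#'
#' Partitions the `n` variants, viewed as m-dimensional VAF vectors, into
#' `T` clusters whose centroids seed the EM restarts. The clustering is run
#' once per dataset (seeded, multi-start) and its centroids are reused for
#' every candidate clone number.
#'
#' @param F `m x n` VAF matrix.
#' @param T Number of clusters (clamped to the number of distinct VAF
#'   vectors, with a warning, when the data cannot support `T`).
#' @param seed Integer seed.
#' @return A list with `centroids` (`m x T` matrix) and `labels`
#'   (per-variant cluster index).
#' @export
kmeans_partition <- function(F, T = 10L, seed = 1L) {
  n <- ncol(F)
  if (n < 2) stop("need at least two variants to initialize", call. = FALSE)
  X <- t(F)
  ndistinct <- nrow(unique(X))
  if (T > ndistinct) {
    warning(sprintf("T = %d exceeds the %d distinct VAF vectors; clamped",
                    T, ndistinct))
    T <- ndistinct
  }
  set.seed(seed)
  km <- kmeans(X, centers = T, nstart = 10L, iter.max = 100L)
  centroids <- t(km$centers)
  keep <- km$size > 0
  list(centroids = centroids[, keep, drop = FALSE], labels = km$cluster)
}

#' Random selection of provisional true-positive clusters
#'
#' Draws `k` of the `T` K-means centroids uniformly without replacement as
#' the provisional true clones for one EM restart, and appends the fixed
#' zero centroid of the false-variant cluster. Distinct restart indices give
#' independent draws; the whole selection is reproducible from `seed`.
#'
#' @param centroids `m x T` centroid matrix from [kmeans_partition()].
#' @param k Number of true clusters to select (`k <= T`).
#' @param restart Restart index (1-based).
#' @param seed Integer seed.
#' @return A list of class `provisional_clone_set` with `tp_centroids`
#'   (`m x k`), `fv_centroid` (zero m-vector), `indices`, `k` and `restart`.
#' @export
select_initial_clones <- function(centroids, k, restart = 1L, seed = 1L) {
  T <- ncol(centroids)
  if (k > T) stop(sprintf("k = %d exceeds the %d available centroids", k, T),
                  call. = FALSE)
  set.seed(derive_seed(seed, 101L, k, restart))
  idx <- sort(sample.int(T, k))
  structure(
    list(
      tp_centroids = centroids[, idx, drop = FALSE],
      fv_centroid = matrix(0, nrow(centroids), 1L),
      indices = idx, k = as.integer(k), restart = as.integer(restart)
    ),
    class = "provisional_clone_set"
  )
}
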