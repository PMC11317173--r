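#' Decomposition run configuration
#'
#' Collects every tunable of the decomposition pipeline with its default.
#' Defaults mirror the method's reference settings: clone numbers are
#' searched over `[2, 10]`, initial K-means uses 10 clusters, each candidate
#' clone number gets 10 random initial-clone selections, EM runs between 10
#' and 20 iterations, the sequencing-error probability defaults to 0.01
#' (Phred 20), the false-positive prior is 0.01 per zero-centroid cluster,
#' true-negative priors sum to 0.99, the structure t-tests use significance
#' level 0.01 and the fuzzy/hard choice uses a posterior Jaccard threshold
#' of 0.2.
#'
#' @param k_min,k_max Inclusive range of candidate clone numbers.
#' @param kmeans_clusters Number of K-means clusters `T` used to seed
#'   initial centroids.
#' @param n_restarts Random initial-clone selections per candidate `k`.
#' @param max_em_iter,min_em_iter EM iteration budget; convergence is only
#'   declared after more than `min_em_iter` iterations.
#' @param p_se_default Sequencing-error probability used when no base
#'   quality is provided.
#' @param fp_prior Prior probability of each zero-centroid cluster when a
#'   variant has non-zero alternate reads.
#' @param tn_prior_total Total prior mass on zero-centroid clusters when a
#'   variant has zero alternate reads.
#' @param c_scale Multiplication constant applied to the beta-binomial
#'   pseudo-counts (increase for over-dispersed data).
#' @param t_test_alpha Significance level of the subclone-rule and sum-rule
#'   multisample t-tests.
#' @param jaccard_threshold Posterior Jaccard similarity above which the
#'   fuzzy solution replaces the hard one.
#' @param gap_b Number of uniform reference datasets for the gap statistic.
#' @param seed Integer seed governing every random choice of the run.
#'
#' @return A list of class `declone_config`.
#' @export
declone_config <- function(k_min = 2L, k_max = 10L, kmeans_clusters = 10L,
                           n_restarts = 10L, max_em_iter = 20L,
                           min_em_iter = 10L, p_se_default = 0.01,
                           fp_prior = 0.01, tn_prior_total = 0.99,
                           c_scale = 1, t_test_alpha = 0.01,
                           jaccard_threshold = 0.2, gap_b = 10L,
                           seed = 1L) {
  stopifnot(
    k_min >= 1, k_max >= k_min,
    kmeans_clusters >= 1, k_max <= max(kmeans_clusters, k_max),
    n_restarts >= 1, max_em_iter >= 1, min_em_iter >= 1,
    p_se_default > 0, p_se_default < 1,
    fp_prior > 0, fp_prior < 1,
    tn_prior_total > 0, tn_prior_total < 1,
    c_scale > 0, t_test_alpha > 0, t_test_alpha < 1,
    jaccard_threshold >= 0, jaccard_threshold <= 1,
    gap_b >= 1
  )
  structure(
    list(
      k_min = as.integer(k_min), k_max = as.integer(k_max),
      kmeans_clusters = as.integer(kmeans_clusters),
      n_restarts = as.integer(n_restarts),
      max_em_iter = as.integer(max_em_iter),
      min_em_iter = as.integer(min_em_iter),
      p_se_default = p_se_default, fp_prior = fp_prior,
      tn_prior_total = tn_prior_total, c_scale = c_scale,
      t_test_alpha = t_test_alpha, jaccard_threshold = jaccard_threshold,
      gap_b = as.integer(gap_b), seed = as.integer(seed)
    ),
    class = "declone_config"
  )
}
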