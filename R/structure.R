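# Clone-structure classification: which clusters are individual subclones
# (their centroids sum to 0.5 per sample), which are ancestral superclones
# (centroid equal to the sum of a set of individual clones), via multisample
# t-tests on cluster-member VAFs.

# Cache of subset enumerations, keyed by k: building ~1000 subsets per
# structure check would otherwise dominate the pipeline's R-level cost.
.subset_cache <- new.env(parent = emptyenv())

subsets_for_k <- function(k) {
  key <- as.character(k)
  hit <- .subset_cache[[key]]
  if (!is.null(hit)) return(hit)
  subsets <- enumerate_candidate_subsets(k)
  S <- matrix(0, length(subsets), k)
  for (i in seq_along(subsets)) S[i, subsets[[i]]] <- 1
  val <- list(subsets = subsets, S = S)
  .subset_cache[[key]] <- val
  val
}

#' Enumerate candidate subsets of true clusters
#'
#' All non-empty subsets of `k` true clusters, ordered by size then
#' lexicographically; each is a candidate set of individual clones.
#'
#' @param k Number of true clusters (at most 10).
#' @return A list of integer vectors.
#' @export
enumerate_candidate_subsets <- function(k) {
  stopifnot(k >= 1, k <= 10)
  out <- list()
  for (s in seq_len(k)) {
    cmb <- combn(k, s)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

# Per-cluster, per-sample membership-weighted VAF statistics. In hard mode
# the weights are one-hot and these are the ordinary per-cluster mean,
# variance and count; in fuzzy mode the effective count is the summed
# membership. The FV column is excluded.
cluster_vaf_stats <- function(F, Theta, fv_index = ncol(Theta)) {
  true_idx <- setdiff(seq_len(ncol(Theta)), fv_index)
  W <- Theta[, true_idx, drop = FALSE]
  n_eff <- colSums(W)
  n_eff_safe <- pmax(n_eff, 1e-12)
  mean_ <- sweep(F %*% W, 2L, n_eff_safe, "/")          # m x k
  ex2 <- sweep((F^2) %*% W, 2L, n_eff_safe, "/")
  var_ <- sweep(ex2 - mean_^2, 2L, n_eff_safe / pmax(n_eff_safe - 1, 1e-12),
                "*")
  var_ <- pmax(var_, 0)
  list(n = n_eff, mean = mean_, var = var_, k = length(true_idx))
}

# Vectorized multisample t-tests for many subsets at once.
# S: nsub x k logical membership matrix; returns per-sample t, p and df
# matrices plus validity/pass vectors. `target` is the null value of the
# centroid sum (0.5 for the subclone rule) or a per-sample vector; extra_var
# and extra_n add a superclone term for the sum rule.
subset_t_tests <- function(stats, S, alpha, target = 0.5,
                           extra_var = NULL, extra_n = NULL) {
  if (!is.double(S)) S <- matrix(as.numeric(S), nrow = NROW(S))
  nsub <- nrow(S)
  m <- nrow(stats$mean)
  size <- rowSums(S)
  minn <- rep(Inf, nsub)
  for (y in seq_len(ncol(S))) {
    sel <- S[, y] > 0
    minn[sel] <- pmin(minn[sel], stats$n[y])
  }
  valid <- minn >= 2
  vn <- sweep(stats$var, 2L, stats$n, "/")              # var/n per cluster
  summean <- S %*% t(stats$mean)                        # nsub x m
  se2 <- S %*% t(vn)
  wnum <- S %*% t(vn^2 / pmax(stats$n - 1, 1e-12))
  if (!is.null(extra_var)) {
    se2 <- sweep(se2, 2L, extra_var / extra_n, "+")
    wnum <- sweep(wnum, 2L, (extra_var / extra_n)^2 /
                    pmax(extra_n - 1, 1e-12), "+")
  }
  se <- sqrt(pmax(se2, 1e-12))
  se <- pmax(se, 1e-6)  # floor for degenerate (all-identical) clusters
  if (is.matrix(target)) {
    tstat <- (summean - target) / se
  } else {
    tstat <- sweep(summean, 2L, rep(target, length.out = m), "-") / se
  }
  # variance-homogeneity gate: two-sample F test between the most and least
  # dispersed cluster in the subset; rejection switches to Welch df
  df_pool <- matrix(rep(as.numeric(S %*% stats$n) - size +
                          (if (is.null(extra_n)) 0 else extra_n - 1),
                        m), nsub, m)
  df_welch <- (se2^2) / pmax(wnum, 1e-300)
  use_welch <- matrix(FALSE, nsub, m)
  for (i in seq_len(m)) {
    vmax <- rep(-Inf, nsub); vmin <- rep(Inf, nsub)
    nmax <- rep(1, nsub); nmin <- rep(1, nsub)
    for (y in seq_len(ncol(S))) {
      sel <- S[, y] > 0
      v <- stats$var[i, y]
      upd <- sel & v > vmax
      vmax[upd] <- v; nmax[upd] <- stats$n[y]
      upd <- sel & v < vmin
      vmin[upd] <- v; nmin[upd] <- stats$n[y]
    }
    if (!is.null(extra_var)) {
      v <- extra_var[i]
      upd <- v > vmax
      vmax[upd] <- v; nmax[upd] <- extra_n
      upd <- v < vmin
      vmin[upd] <- v; nmin[upd] <- extra_n
    }
    ratio <- vmax / pmax(vmin, 1e-300)
    pf_hi <- pf(ratio, pmax(nmax - 1, 1), pmax(nmin - 1, 1),
                lower.tail = FALSE)
    multi <- (size + (if (is.null(extra_n)) 0 else 1)) > 1
    use_welch[, i] <- multi & (2 * pf_hi < 0.05)
  }
  df <- ifelse(use_welch, df_welch, pmax(df_pool, 1))
  df <- pmax(df, 1)
  p <- 2 * pt(-abs(tstat), df)
  # Bonferroni split across samples keeps the multisample test at level
  # alpha: a subset fails only when some sample rejects at alpha / m
  pass <- valid & (rowSums(p > alpha / m) == m)
  cp <- p[, 1L]
  for (i in seq_len(m)[-1L]) cp <- pmin(cp, p[, i])
  list(t = tstat, p = p, df = df, valid = valid, pass = pass,
       combined_p = cp, size = size)
}

new_combination_test <- function(subset, tt, row = 1L) {
  structure(
    list(
      cluster_subset = subset,
      per_sample_t = tt$t[row, ],
      per_sample_p = tt$p[row, ],
      df = tt$df[row, ],
      pass = tt$pass[row] && tt$valid[row],
      combined_p = if (tt$valid[row]) tt$combined_p[row] else NA_real_
    ),
    class = "combination_test"
  )
}

#' Subclone-rule test for one candidate subset
#'
#' Tests, per sample, the null hypothesis that the centroids of the chosen
#' clusters sum to 0.5 (heterozygous variants, total cellular prevalence
#' one). The t statistic divides the deviation of the summed cluster means
#' from 0.5 by the standard error of the sum; degrees of freedom are pooled
#' (`sum(n) - k'`) unless a variance-homogeneity F test rejects at 0.05, in
#' which case the Welch-Satterthwaite approximation is used. The subset
#' passes when no sample rejects at the Bonferroni-split per-sample level
#' `alpha / m`, keeping the multisample test at its stated level; subsets
#' containing a cluster
#' with fewer than two member variants are rejected outright.
#'
#' @param F `m x n` VAF matrix.
#' @param Theta `n x (k+1)` membership matrix (FV column last); fuzzy
#'   memberships enter as weights with effective counts.
#' @param subset Integer vector of true-cluster indices.
#' @param alpha Significance level (default 0.01).
#' @return A `combination_test` with per-sample t, p and df, the pass flag
#'   and the combined (minimum) p-value.
#' @export
subclone_rule_test <- function(F, Theta, subset, alpha = 0.01) {
  stats <- cluster_vaf_stats(F, Theta)
  S <- matrix(0, 1L, stats$k)
  S[1, subset] <- 1
  new_combination_test(sort(subset), subset_t_tests(stats, S, alpha))
}

#' Choose the individual-clone set
#'
#' Among all candidate subsets that pass the subclone rule, selects the one
#' with the highest combined p-value (the subset supporting the null most
#' strongly); ties break toward larger subsets, then lexicographically.
#'
#' @param tests A list of `combination_test` objects (one per candidate
#'   subset), e.g. from [subclone_rule_test()].
#' @param alpha Significance level, used only for validation.
#' @return The winning `combination_test`, or `NULL` when no subset passes
#'   (the caller restarts from a new provisional clone set).
#' @export
select_individual_clones <- function(tests, alpha = 0.01) {
  passing <- Filter(function(t) isTRUE(t$pass), tests)
  if (length(passing) == 0) return(NULL)
  best <- NULL
  for (t in passing) {
    if (is.null(best) ||
        t$combined_p > best$combined_p + 1e-15 ||
        (abs(t$combined_p - best$combined_p) <= 1e-15 &&
         (length(t$cluster_subset) > length(best$cluster_subset) ||
          (length(t$cluster_subset) == length(best$cluster_subset) &&
           paste(t$cluster_subset, collapse = ",") <
           paste(best$cluster_subset, collapse = ","))))) {
      best <- t
    }
  }
  best
}

#' Sum-rule test for a superclone candidate
#'
#' Tests, per sample, the null hypothesis that the candidate superclone's
#' centroid equals the sum of the centroids of a subset of individual
#' clones; standard errors combine the superclone's and the subclones'
#' mean-variances, with the same pooled/Welch degree-of-freedom choice as
#' the subclone rule.
#'
#' @inheritParams subclone_rule_test
#' @param superclone Index of the candidate ancestral cluster (not in the
#'   individual set).
#' @param subclone_subset Integer vector of at least two individual-clone
#'   indices.
#' @return A `combination_test`.
#' @export
sum_rule_test <- function(F, Theta, superclone, subclone_subset,
                          alpha = 0.01) {
  stats <- cluster_vaf_stats(F, Theta)
  S <- matrix(0, 1L, stats$k)
  S[1, subclone_subset] <- 1
  tt <- subset_t_tests(stats, S, alpha,
                       target = matrix(stats$mean[, superclone], 1L,
                                       nrow(stats$mean), byrow = FALSE),
                       extra_var = stats$var[, superclone],
                       extra_n = stats$n[superclone])
  out <- new_combination_test(sort(subclone_subset), tt)
  out$pass <- out$pass && stats$n[superclone] >= 2
  out$superclone <- superclone
  out
}

#' Classify clusters and build the superclone phylogeny
#'
#' Given the selected individual clones, every remaining true cluster must
#' be explainable as an ancestral superclone: its centroid must match, by
#' the sum rule, the summed centroids of some subset (of size at least two)
#' of individual clones. Each superclone is linked to the passing subset of
#' highest combined p; a cluster with no passing subset triggers a restart.
#'
#' @inheritParams subclone_rule_test
#' @param individual Integer vector of individual-clone indices (from
#'   [select_individual_clones()]).
#' @param subclone_p Combined p-value of the winning subclone-rule test
#'   (stored on the result).
#' @return A `clone_structure` list (individual, ancestral, fv_index,
#'   edges tibble, p-values), or `NULL` as a restart signal.
#' @export
build_phylogeny <- function(F, Theta, individual, alpha = 0.01,
                            subclone_p = NA_real_) {
  stats <- cluster_vaf_stats(F, Theta)
  k <- stats$k
  remaining <- setdiff(seq_len(k), individual)
  edges <- tibble::tibble(superclone = integer(), subclones = list(),
                          combined_p = numeric())
  if (length(remaining) > 0 && length(individual) < 2) return(NULL)
  cand <- NULL
  if (length(remaining) > 0) {
    all_sub <- subsets_for_k(length(individual))
    keep <- lengths(all_sub$subsets) >= 2
    if (!any(keep)) return(NULL)
    subsets <- all_sub$subsets[keep]
    S <- matrix(0, length(subsets), k)
    S[, individual] <- all_sub$S[keep, , drop = FALSE]
    cand <- list(subsets = subsets, S = S)
  }
  for (z in remaining) {
    if (stats$n[z] < 2) return(NULL)
    subsets <- cand$subsets
    S <- cand$S
    tt <- subset_t_tests(stats, S, alpha,
                         target = matrix(rep(stats$mean[, z], each = nrow(S)),
                                         nrow(S), nrow(stats$mean)),
                         extra_var = stats$var[, z], extra_n = stats$n[z])
    ok <- which(tt$pass & tt$valid)
    if (length(ok) == 0) return(NULL)
    best <- ok[which.max(tt$combined_p[ok])]
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      superclone = z, subclones = list(individual[subsets[[best]]]),
      combined_p = tt$combined_p[best]))
  }
  structure(
    list(
      individual = sort(individual),
      ancestral = sort(remaining),
      fv_index = ncol(Theta),
      edges = edges,
      subclone_rule_p = subclone_p,
      sum_rule_p = edges$combined_p
    ),
    class = "clone_structure"
  )
}

# Fast path used inside the pipeline: finds the best-passing individual
# subset (restart signal = NULL) without materializing per-subset objects.
best_individual_subset <- function(stats, alpha) {
  k <- stats$k
  all_sub <- subsets_for_k(k)
  subsets <- all_sub$subsets
  S <- all_sub$S
  tt <- subset_t_tests(stats, S, alpha)
  ok <- which(tt$pass & tt$valid)
  if (length(ok) == 0) return(NULL)
  # highest combined p; ties toward larger subsets then lexicographic order
  # (the enumeration is already lexicographic within size)
  best <- ok[order(-tt$combined_p[ok], -tt$size[ok], ok)][1]
  list(subset = subsets[[best]], combined_p = tt$combined_p[best])
}

# Full structure check for a converged model; NULL = restart signal.
# theta_sum carries the membership used for the sum-rule tests: fuzzy
# models pass their hardened (argmax) membership there, because
# fuzzy-weighted variances are inflated by posterior sharing and make the
# superclone test too weak to reject spurious ancestral explanations.
check_clone_structure <- function(F, Theta, alpha, theta_sum = Theta) {
  stats <- cluster_vaf_stats(F, Theta)
  sel <- best_individual_subset(stats, alpha)
  if (is.null(sel)) return(NULL)
  build_phylogeny(F, theta_sum, sel$subset, alpha,
                  subclone_p = sel$combined_p)
}
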