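# Finalization: choose the clone number with a gap-statistic criterion over
# the hard-clustering solutions, decide hard vs fuzzy output by posterior
# overlap, and flag false variants.

#' Gap-statistic selection of the clone number
#'
#' For each feasible candidate `k`, the within-cluster dispersion `W_k` is
#' the summed squared Euclidean distance of each variant's m-dimensional
#' VAF vector to its hard-assigned centroid (variants assigned to the FV
#' cluster are excluded). `B` reference datasets of the same size, drawn
#' uniformly over the observed per-dimension VAF range, are clustered with
#' K-means at the same `k`; the starred gap is the mean reference dispersion
#' minus the observed dispersion on the absolute (non-logarithmic) scale,
#' and the `k` with the largest gap wins (ties to the smaller `k`).
#'
#' @param models Named list of converged hard-mode `clone_model`s, one per
#'   feasible `k` (names are the candidate `k` values).
#' @param F `m x n` VAF matrix.
#' @param B Number of reference datasets (default 10).
#' @param seed Integer seed for the reference draws.
#' @return A list with `chosen_k` and `report`, a tibble with one row per
#'   candidate (`k`, `W`, `ref_W_mean`, `ref_W_se`, `gap`).
#' @export
gap_star_select_k <- function(models, F, B = 10L, seed = 1L) {
  stopifnot(length(models) >= 1)
  ks <- as.integer(names(models))
  m <- nrow(F)
  n <- ncol(F)
  lo <- apply(F, 1L, min)
  hi <- apply(F, 1L, max)
  set.seed(derive_seed(seed, 577L))
  refs <- lapply(seq_len(B), function(b) {
    vapply(seq_len(m), function(i) runif(n, lo[i], hi[i]), numeric(n))
  })
  rows <- vector("list", length(ks))
  memo <- new.env(parent = emptyenv()) # candidates sharing an effective k
  for (q in seq_along(ks)) {
    model <- models[[q]]
    K <- ncol(model$Theta)
    assign <- max.col(model$Theta, ties.method = "first")
    tv <- assign != K
    k_eff <- model$k
    # observed and reference dispersions from the same K-means procedure at
    # this k (false-variant-assigned points excluded on the observed side),
    # so the gap compares like with like across candidates
    X_tv <- t(F[, tv, drop = FALSE])
    kk <- min(k_eff, nrow(unique(X_tv)))
    key <- paste0(kk, ":", sum(tv))
    hit <- memo[[key]]
    if (is.null(hit)) {
      W <- kmeans(X_tv, centers = kk, nstart = 3L,
                  iter.max = 30L)$tot.withinss
      ref_W <- vapply(refs, function(X) {
        km <- kmeans(X, centers = min(kk, nrow(unique(X))), nstart = 3L,
                     iter.max = 30L)
        km$tot.withinss
      }, numeric(1))
      hit <- list(W = W, ref_W = ref_W)
      memo[[key]] <- hit
    }
    rows[[q]] <- tibble::tibble(
      k = ks[q], W = hit$W,
      ref_W_mean = mean(hit$ref_W),
      ref_W_se = stats::sd(hit$ref_W) * sqrt(1 + 1 / B),
      gap = mean(hit$ref_W) - hit$W)
  }
  report <- dplyr::bind_rows(rows)
  chosen <- report$k[order(-report$gap, report$k)][1]
  list(chosen_k = chosen, report = report)
}

#' Maximum pairwise posterior Jaccard overlap
#'
#' Soft Jaccard similarity between the posterior columns of every pair of
#' true clusters: `sum(pmin) / sum(pmax)` over variants. High overlap means
#' two clones compete for the same variants, in which case fuzzy membership
#' is the more faithful output.
#'
#' @param Lambda Row-normalized `n x (k+1)` posterior matrix, FV last.
#' @return Maximum pairwise Jaccard similarity (0 when fewer than two true
#'   clusters).
#' @export
pairwise_posterior_jaccard <- function(Lambda) {
  k <- ncol(Lambda) - 1L
  if (k < 2) return(0)
  best <- 0
  for (y1 in seq_len(k - 1L)) {
    for (y2 in seq((y1 + 1L), k)) {
      denom <- sum(pmax(Lambda[, y1], Lambda[, y2]))
      if (denom <= 0) next
      j <- sum(pmin(Lambda[, y1], Lambda[, y2])) / denom
      best <- max(best, j)
    }
  }
  best
}

#' Choose between the hard and fuzzy solutions
#'
#' The fuzzy solution is reported when the hard solution's posterior shows
#' genuinely overlapping clones — maximum pairwise Jaccard strictly above
#' the threshold (default 0.2); otherwise the hard solution is retained.
#' A missing fuzzy model falls back to hard with a warning.
#'
#' @param hard_model,fuzzy_model Converged `clone_model`s at the chosen `k`.
#' @param threshold Jaccard threshold (strict inequality).
#' @return A list with `model`, `mode` and `max_jaccard`.
#' @export
choose_mode <- function(hard_model, fuzzy_model, threshold = 0.2) {
  j <- pairwise_posterior_jaccard(hard_model$Lambda)
  if (j > threshold) {
    if (is.null(fuzzy_model)) {
      warning("fuzzy model unavailable; retaining hard clustering")
      return(list(model = hard_model, mode = "hard", max_jaccard = j))
    }
    return(list(model = fuzzy_model, mode = "fuzzy", max_jaccard = j))
  }
  list(model = hard_model, mode = "hard", max_jaccard = j)
}

#' Label false variants
#'
#' A variant is a false variant (FV) when the FV cluster maximizes its
#' membership row; everything else is a true variant (TV).
#'
#' @param model A finalized `clone_model`.
#' @return Character vector of `"TV"` / `"FV"`, one per variant.
#' @export
label_false_variants <- function(model) {
  K <- ncol(model$Theta)
  idx <- max.col(model$Theta, ties.method = "first")
  ifelse(idx == K, "FV", "TV")
}
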