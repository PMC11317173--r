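# Evaluation of decomposition outputs against a known truth: clone-number
# RMSE, adjusted Rand index, best-injection membership score and
# false-variant isolation.

#' Contingency table between two labelings
#'
#' Shared-variant counts `u[i, j]` between answer cluster `i` and predicted
#' cluster `j`, with row/column totals.
#'
#' @param truth,pred Label vectors of equal length (characters or factors).
#' @return A list with `u` (matrix), `a` (row sums), `p` (column sums) and
#'   `n`.
#' @export
contingency_table <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  u <- unclass(table(truth, pred))
  list(u = u, a = rowSums(u), p = colSums(u), n = length(truth))
}

#' Clone-number root-mean-square error
#'
#' @param predicted,truth Equal-length integer vectors of estimated and
#'   true clone numbers across trials.
#' @return `sqrt(mean((predicted - truth)^2))`.
#' @export
clone_number_rmse <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1) {
    stop("predicted and truth must be equal-length, non-empty", call. = FALSE)
  }
  sqrt(mean((predicted - truth)^2))
}

#' Adjusted Rand index
#'
#' Chance-corrected partition agreement computed from the pair-counting
#' contingency table. Degenerate case (a single cluster on both sides, so
#' the expected index equals the maximum) returns 1.
#'
#' @param truth,pred Label vectors, or `truth` may be a contingency list
#'   from [contingency_table()] with `pred` missing.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth, pred = NULL) {
  ct <- if (is.list(truth) && !is.null(truth$u)) truth else
    contingency_table(truth, pred)
  n <- ct$n
  if (n < 2) stop("need at least two observations", call. = FALSE)
  sum_u <- sum(choose(ct$u, 2))
  sum_a <- sum(choose(ct$a, 2))
  sum_p <- sum(choose(ct$p, 2))
  expected <- sum_a * sum_p / choose(n, 2)
  maxi <- (sum_a + sum_p) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_u - expected) / (maxi - expected)
}

# Exact maximum-weight injection by bitmask dynamic programming: rows of u
# are matched injectively into columns (the smaller side is made the rows),
# maximizing the total shared count. Returns the optimal weight and the
# realizing injection as a truth-label -> predicted-label map.
sm_assignment <- function(u) {
  ta <- rownames(u)
  tp <- colnames(u)
  transposed <- nrow(u) > ncol(u)
  if (transposed) u <- t(u)
  nr <- nrow(u)
  nc <- ncol(u)
  nstate <- bitwShiftL(1L, nc)
  dp <- matrix(-Inf, nr + 1L, nstate)
  dp[1L, 1L] <- 0
  choice <- matrix(NA_integer_, nr + 1L, nstate)
  from <- matrix(NA_integer_, nr + 1L, nstate)
  for (r in seq_len(nr)) {
    for (s in which(is.finite(dp[r, ]))) {
      mask <- s - 1L
      for (cc in seq_len(nc)) {
        bit <- bitwShiftL(1L, cc - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        t <- bitwOr(mask, bit) + 1L
        v <- dp[r, s] + u[r, cc]
        if (v > dp[r + 1L, t]) {
          dp[r + 1L, t] <- v
          choice[r + 1L, t] <- cc
          from[r + 1L, t] <- s
        }
      }
    }
  }
  s <- which.max(dp[nr + 1L, ])
  weight <- dp[nr + 1L, s]
  map <- integer(nr)
  for (r in rev(seq_len(nr))) {
    map[r] <- choice[r + 1L, s]
    s <- from[r + 1L, s]
  }
  rows <- if (transposed) tp else ta   # labels of the smaller (row) side
  cols <- if (transposed) ta else tp
  if (transposed) {
    inj <- setNames(rep(NA_character_, length(ta)), ta)
    inj[cols[map]] <- rows
  } else {
    inj <- setNames(cols[map], rows)
  }
  list(weight = weight, injection = inj)
}

max_injection_weight <- function(u) sm_assignment(u)$weight

#' Membership score
#'
#' The maximum percentage of variants placed in matching clusters over all
#' injective mappings between the answer and predicted cluster index sets
#' (the smaller side maps injectively into the larger). Unlike the ARI it
#' treats the false-variant cluster as a labeled cluster on both sides, so
#' it rewards exact FV discrimination.
#'
#' @param truth,pred Label vectors, or `truth` may be a contingency list
#'   from [contingency_table()] with `pred` missing.
#' @return Score in `[0, 100]`.
#' @export
membership_score <- function(truth, pred = NULL) {
  ct <- if (is.list(truth) && !is.null(truth$u)) truth else
    contingency_table(truth, pred)
  100 * max_injection_weight(ct$u) / ct$n
}

#' Was the false-variant cluster isolated?
#'
#' `TRUE` when, under the membership-score injection, the predicted cluster
#' matched to the truth FV cluster is the predicted FV cluster and it
#' captures more than half of the true false variants.
#'
#' @param pred,truth Label vectors; false variants labeled `fv_label`.
#' @param fv_label Label marking false variants (default `"FV"`).
#' @return `TRUE`/`FALSE`, or `NA` when the truth contains no false
#'   variant.
#' @export
fv_isolation_detected <- function(pred, truth, fv_label = "FV") {
  if (!any(truth == fv_label)) return(NA)
  ct <- contingency_table(truth, pred)
  if (!fv_label %in% colnames(ct$u)) return(FALSE)
  inj <- sm_assignment(ct$u)$injection
  matched <- unname(inj[fv_label])
  if (is.na(matched) || matched != fv_label) return(FALSE)
  recall <- sum(pred == fv_label & truth == fv_label) / sum(truth == fv_label)
  recall > 0.5
}

#' Score a decomposition against simulated truth
#'
#' Hardens fuzzy memberships by per-variant argmax, then reports the
#' predicted and true clone numbers, ARI, membership score and the FV
#' isolation flag.
#'
#' @param fit A `declone_fit`.
#' @param truth Truth tibble from [generate_sim_dataset()] (`variant_id`,
#'   `clone`), in the same variant order as the fitted table.
#' @return One-row tibble of scores.
#' @export
evaluate_decomposition <- function(fit, truth) {
  stopifnot(identical(truth$variant_id, fit$membership$variant_id))
  pred <- ifelse(fit$membership$flag == "FV", "FV", fit$membership$cluster)
  k_true <- length(setdiff(unique(truth$clone), "FV"))
  tibble::tibble(
    k_true = k_true,
    k_pred = fit$chosen_k,
    ari = adjusted_rand_index(truth$clone, pred),
    s_m = membership_score(truth$clone, pred),
    fv_isolated = fv_isolation_detected(pred, truth$clone)
  )
}
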