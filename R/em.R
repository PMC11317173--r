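# Reference (plain R) implementation of the EM engine. The pipeline uses the
# compiled kernel in src/em.cpp; both paths are asserted to agree in the test
# suite. Matrices are samples x variants (m x n); centroid matrices are
# m x (k + 1) with the false-variant (FV) column, fixed at 0, last.

# Context-dependent log prior over clusters for one sample.
# Case selection is keyed on (n_alt == 0?, centroid == 0?): with non-zero
# alternate reads a zero-centroid cluster gets fp_prior each and the
# remaining mass is split over the non-zero-centroid clusters; with zero
# alternate reads the zero-centroid clusters share tn_prior_total and the
# remainder is split over the others.
log_context_priors <- function(mu_row, alt_is_zero, fp_prior,
                               tn_prior_total) {
  zero <- mu_row == 0
  nzero <- sum(zero)
  nz <- sum(!zero)
  lp <- numeric(length(mu_row))
  if (nzero == 0 || nz == 0) {
    stop("centroid matrix must contain zero and non-zero centroid clusters",
         call. = FALSE)
  }
  if (alt_is_zero) {
    lp[zero] <- log(tn_prior_total / nzero)
    lp[!zero] <- log((1 - tn_prior_total) / nz)
  } else {
    lp[zero] <- log(fp_prior)
    lp[!zero] <- log((1 - nzero * fp_prior) / nz)
  }
  lp
}

# Per-sample log numerators: log-likelihood + log-prior for each variant and
# cluster. alt/total are integer vectors over variants for one sample.
sample_lognum <- function(alt_i, total_i, mu_row, p_se, fp_prior,
                          tn_prior_total, c_scale) {
  n <- length(alt_i)
  K <- length(mu_row)
  lp_pos <- log_context_priors(mu_row, FALSE, fp_prior, tn_prior_total)
  lp_zero <- log_context_priors(mu_row, TRUE, fp_prior, tn_prior_total)
  s <- matrix(0, n, K)
  informative <- total_i > 0L
  for (y in seq_len(K)) {
    ll <- numeric(n)
    if (mu_row[y] == 0) {
      ll[informative] <- dbinom(alt_i[informative], total_i[informative],
                                p_se[informative], log = TRUE)
    } else {
      ll[informative] <- log(betabin_likelihood(
        alt_i[informative], total_i[informative], mu_row[y], c_scale))
    }
    s[, y] <- ll + ifelse(alt_i == 0L, lp_zero[y], lp_pos[y])
  }
  s
}

#' E step: per-sample and combined posterior cluster probabilities
#'
#' For every variant and cluster the posterior is proportional to
#' likelihood times prior, with the likelihood chosen by case: non-zero
#' alternate reads against a non-zero centroid use the beta-binomial
#' (true positive); against the zero centroid the binomial error model
#' (false positive); zero alternate reads use the same two likelihoods in
#' the false-negative / true-negative roles with the true-negative prior
#' mass at 0.99. Per-sample posteriors are multiplied across samples and
#' renormalized to give the combined posterior. Zero-depth entries
#' contribute a factor of one.
#'
#' @param table A [variant_table].
#' @param centroids `m x (k+1)` centroid matrix, zero FV column last.
#' @param config A [declone_config()].
#' @return A list with `lambda` (list of `n x (k+1)` per-sample posterior
#'   matrices), `Lambda` (combined `n x (k+1)` posterior) and `lognum`
#'   (summed log numerators, used by [map_objective()]).
#' @export
e_step <- function(table, centroids, config = declone_config()) {
  alt <- alt_counts(table)
  tot <- total_counts(table)
  p_se <- p_se_values(table, config$p_se_default)
  m <- nrow(alt)
  lambda <- vector("list", m)
  lognum <- NULL
  for (i in seq_len(m)) {
    s <- sample_lognum(alt[i, ], tot[i, ], centroids[i, ], p_se,
                       config$fp_prior, config$tn_prior_total,
                       config$c_scale)
    lambda[[i]] <- row_softmax(s)
    lognum <- if (is.null(lognum)) s else lognum + s
  }
  names(lambda) <- sample_ids(table)
  list(lambda = lambda, Lambda = row_softmax(lognum), lognum = lognum)
}

#' Membership assignment from the combined posterior
#'
#' Hard clustering assigns each variant a one-hot membership at the
#' posterior argmax (ties broken toward the lower cluster index); fuzzy
#' clustering takes the posterior itself as membership.
#'
#' @param Lambda Row-normalized `n x (k+1)` posterior matrix.
#' @param mode `"hard"` or `"fuzzy"`.
#' @return `n x (k+1)` membership matrix `Theta`.
#' @export
assign_membership <- function(Lambda, mode = c("hard", "fuzzy")) {
  mode <- match.arg(mode)
  if (mode == "fuzzy") return(Lambda)
  idx <- max.col(Lambda, ties.method = "first")
  Theta <- matrix(0, nrow(Lambda), ncol(Lambda), dimnames = dimnames(Lambda))
  Theta[cbind(seq_len(nrow(Lambda)), idx)] <- 1
  Theta
}

#' M step: membership-weighted centroid update
#'
#' Each true cluster's per-sample centroid becomes the membership-weighted
#' mean VAF of its variants; the FV centroid stays fixed at zero. A true
#' cluster whose total membership falls below `1e-12` is dropped with a
#' warning (the candidate clone number shrinks).
#'
#' @param F `m x n` VAF matrix.
#' @param Theta `n x (k+1)` membership matrix, FV column last.
#' @return A list with `centroids` (`m x (k'+1)`), `dropped` (indices of
#'   removed true clusters) and `aborted` (TRUE when no true cluster
#'   survives).
#' @export
m_step <- function(F, Theta) {
  K <- ncol(Theta)
  true_idx <- seq_len(K - 1L)
  w <- colSums(Theta[, true_idx, drop = FALSE])
  keep <- w >= 1e-12
  if (!any(keep)) {
    return(list(centroids = NULL, dropped = true_idx, aborted = TRUE))
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d empty cluster(s) during M step",
                    sum(!keep)))
  }
  num <- F %*% Theta[, true_idx[keep], drop = FALSE]
  mu_true <- sweep(num, 2L, w[keep], "/")
  list(centroids = cbind(mu_true, 0), dropped = true_idx[!keep],
       aborted = FALSE)
}

#' Marginal log-posterior objective
#'
#' The quantity used to rank converged EM runs across restarts: the sum over
#' variants of the log of the prior-weighted likelihood marginalized over
#' clusters (samples multiplied together).
#'
#' @inheritParams e_step
#' @return Scalar log objective.
#' @export
map_objective <- function(table, centroids, config = declone_config()) {
  lognum <- e_step(table, centroids, config)$lognum
  sum(apply(lognum, 1L, logsumexp))
}

#' EM stopping rule
#'
#' Convergence requires more than `min_em_iter` completed iterations AND any
#' of: relative objective change below 1%, every centroid coordinate moving
#' less than 0.01, or an unchanged membership matrix. Independently the
#' iteration halts at `max_em_iter`.
#'
#' @param history List of per-iteration records, each with elements
#'   `objective`, `centroids` and `theta`.
#' @param config A [declone_config()].
#' @return `TRUE` when the stopping conditions are met.
#' @export
check_convergence <- function(history, config = declone_config()) {
  it <- length(history)
  if (it < 2L || it <= config$min_em_iter) return(FALSE)
  cur <- history[[it]]
  prev <- history[[it - 1L]]
  b1 <- abs(cur$objective - prev$objective) < 0.01 * abs(prev$objective)
  b2 <- identical(dim(cur$centroids), dim(prev$centroids)) &&
    max(abs(cur$centroids - prev$centroids)) < 0.01
  b3 <- identical(dim(cur$theta), dim(prev$theta)) &&
    max(abs(cur$theta - prev$theta)) < 1e-12
  isTRUE(b1) || isTRUE(b2) || isTRUE(b3)
}

new_clone_model <- function(centroids, Lambda, Theta, mode, objective,
                            objective_trace, n_iter, converged,
                            sample_id = NULL, variant_id = NULL) {
  structure(
    list(
      k = ncol(centroids) - 1L,
      centroids = centroids,
      Lambda = Lambda,
      Theta = Theta,
      mode = mode,
      objective = objective,
      objective_trace = objective_trace,
      n_iter = n_iter,
      converged = converged,
      sample_id = sample_id,
      variant_id = variant_id
    ),
    class = "clone_model"
  )
}

#' @export
print.clone_model <- function(x, ...) {
  cat(sprintf(
    "<clone_model> k = %d (+FV), mode = %s, %d EM iterations%s, objective = %.2f\n",
    x$k, x$mode, x$n_iter, if (x$converged) " (converged)" else "",
    x$objective))
  invisible(x)
}

#' Run one EM fit from a provisional clone set
#'
#' Alternates the E step, membership assignment and M step from the given
#' initial centroids until the stopping rule fires or the iteration budget
#' is exhausted, then refreshes the posterior at the final centroids. The
#' compiled engine is the default; `engine = "r"` runs the plain-R steps
#' above (used to cross-check the kernel).
#'
#' @param table A [variant_table].
#' @param provisional A provisional clone set from
#'   [select_initial_clones()], or any `m x (k+1)` centroid matrix with the
#'   zero FV column last.
#' @param mode `"hard"` or `"fuzzy"` clustering.
#' @param config A [declone_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A `clone_model`, or `NULL` when every true cluster empties out
#'   (the caller restarts from a new provisional set).
#' @export
run_em <- function(table, provisional, mode = c("hard", "fuzzy"),
                   config = declone_config(), engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  mu0 <- if (is.matrix(provisional)) provisional else
    cbind(provisional$tp_centroids, provisional$fv_centroid)
  alt <- alt_counts(table)
  tot <- total_counts(table)
  F <- compute_vaf(table)
  p_se <- p_se_values(table, config$p_se_default)
  if (engine == "cpp") {
    fit <- cpp_run_em(alt, tot, F, mu0, p_se, config$fp_prior,
                      config$tn_prior_total, config$c_scale,
                      mode == "hard", config$max_em_iter,
                      config$min_em_iter)
    if (isTRUE(fit$aborted)) return(NULL)
    return(new_clone_model(fit$mu, fit$Lambda, fit$Theta, mode,
                           fit$objective, fit$objective_trace, fit$n_iter,
                           fit$converged, sample_ids(table),
                           variant_ids(table)))
  }
  mu <- clamp_true_centroids(mu0)
  history <- list()
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_em_iter)) {
    es <- e_step(table, mu, config)
    obj <- sum(apply(es$lognum, 1L, logsumexp))
    Theta <- assign_membership(es$Lambda, mode)
    ms <- m_step(F, Theta)
    if (ms$aborted) return(NULL)
    mu <- clamp_true_centroids(ms$centroids)
    if (length(ms$dropped) > 0) {
      Theta <- Theta[, -ms$dropped, drop = FALSE]
    }
    history[[it]] <- list(objective = obj, centroids = mu, theta = Theta)
    trace <- c(trace, obj)
    if (it >= 2) {
      prev <- history[[it - 1L]]
      # exact fixed point: all later iterates are identical, so the
      # stopping rule would fire unchanged at the iteration floor
      if (identical(dim(mu), dim(prev$centroids)) &&
          all(mu == prev$centroids) &&
          identical(dim(Theta), dim(prev$theta)) &&
          all(Theta == prev$theta)) {
        converged <- TRUE
        break
      }
    }
    if (check_convergence(history, config)) {
      converged <- TRUE
      break
    }
  }
  es <- e_step(table, mu, config)
  Theta <- assign_membership(es$Lambda, mode)
  obj <- sum(apply(es$lognum, 1L, logsumexp))
  new_clone_model(mu, es$Lambda, Theta, mode, obj, c(trace, obj),
                  length(history), converged, sample_ids(table),
                  variant_ids(table))
}

clamp_true_centroids <- function(mu) {
  K <- ncol(mu)
  mu[, seq_len(K - 1L)] <- pmin(pmax(mu[, seq_len(K - 1L), drop = FALSE],
                                     1e-6), 1 - 1e-6)
  mu[, K] <- 0
  mu
}
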