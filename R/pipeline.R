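#' Decompose a variant table into subclones
#'
#' Full decomposition pipeline: sex-chromosome depth calibration, K-means
#' initialization, hard-mode EM over the candidate clone-number range with
#' random restarts, structure validation (subclone rule and sum rule),
#' gap-statistic selection of the clone number, a fuzzy-mode EM at the
#' chosen clone number, posterior-overlap choice between hard and fuzzy
#' output, and false-variant labelling.
#'
#' @param table A [variant_table].
#' @param config A [declone_config()]; `config$seed` governs every random
#'   draw, so identical inputs and seed reproduce the fit exactly.
#' @return A `declone_fit` object; see [tidy.declone_fit()],
#'   [glance.declone_fit()], [autoplot.declone_fit()] and
#'   [write_decomposition()].
#' @export
#' @examples
#' sim <- generate_sim_dataset(sim_config(k = 2, m = 1, n = 120, seed = 7))
#' fit <- declone(sim$table, declone_config(k_max = 4, seed = 7))
#' glance(fit)
declone <- function(table, config = declone_config()) {
  stopifnot(inherits(table, "variant_table"))
  if (!isTRUE(attr(table, "calibrated"))) {
    table <- suppressWarnings(calibrate_sex_chromosomes(table))
  }
  F <- compute_vaf(table)
  mats <- list(
    alt = alt_counts(table), total = total_counts(table), F = F,
    p_se = p_se_values(table, config$p_se_default)
  )
  km <- kmeans_partition(F, config$kmeans_clusters,
                         derive_seed(config$seed, 11L))
  ks <- seq(config$k_min, min(config$k_max, ncol(km$centroids)))

  hard <- lapply(ks, function(k) {
    fit_mode_k(mats, km$centroids, k, "hard", config)
  })
  names(hard) <- ks
  hard_ok <- !vapply(hard, function(h) is.null(h$best), logical(1))

  # Where no hard restart satisfies the structure rules, agglomerated
  # clones may still admit a structure-consistent fuzzy fit at that k.
  # The fuzzy route is granted only near or below the smallest feasible
  # candidate found so far: a larger candidate should not become feasible
  # through the statistically weaker fuzzy tests when a smaller candidate
  # already explains the data (parsimony; overlap-driven overestimation
  # was the dominant error mode of the unrestricted rule).
  fuzzy <- setNames(vector("list", length(ks)), ks)
  fuzzy_ok <- logical(length(ks))
  min_feas <- if (any(hard_ok)) min(ks[hard_ok]) else Inf
  for (q in seq_along(ks)) {
    if (hard_ok[q] || ks[q] > min_feas + 2L) next
    fuzzy[[q]] <- fit_mode_k(mats, km$centroids, ks[q], "fuzzy", config)
    fuzzy_ok[q] <- !is.null(fuzzy[[q]]$best)
    if (fuzzy_ok[q]) min_feas <- min(min_feas, ks[q])
  }
  feasible <- hard_ok | fuzzy_ok

  # Before accepting the smallest feasible clone number, give the
  # candidates just below it a second wave of provisional clone sets (the
  # restart-on-failure rule), so an overestimate cannot win merely because
  # the first draws at a smaller k missed its convergence basin.
  wave2_ks <- if (any(feasible)) {
    which(!feasible & ks < min(ks[feasible]) & ks >= min(ks[feasible]) - 2L)
  } else {
    seq_along(ks)
  }
  for (q in wave2_ks) {
    wave2 <- config$n_restarts + seq_len(config$n_restarts)
    h2 <- fit_mode_k(mats, km$centroids, ks[q], "hard", config,
                     restarts = wave2)
    if (!is.null(h2$best)) {
      hard[[q]] <- h2
      hard_ok[q] <- TRUE
    } else {
      f2 <- fit_mode_k(mats, km$centroids, ks[q], "fuzzy", config,
                       restarts = wave2)
      if (!is.null(f2$best)) {
        fuzzy[[q]] <- f2
        fuzzy_ok[q] <- TRUE
      }
    }
  }
  feasible <- hard_ok | fuzzy_ok

  forced <- FALSE
  if (any(feasible)) {
    models <- lapply(which(feasible), function(q) {
      h <- hard[[q]]
      # dispersion comes from the structure-accepted model at this k
      (h$best %||% fuzzy[[q]]$best %||% h$best_any)$model
    })
    names(models) <- ks[feasible]
    sel <- gap_star_select_k(models, F, config$gap_b, config$seed)
    chosen_k <- sel$chosen_k
    q <- match(chosen_k, ks)
    hard_best <- hard[[q]]$best %||% hard[[q]]$best_any
  } else {
    # no candidate clone number admits a structure-consistent solution;
    # fall back to the best-objective run and force a structure on it
    warning("no candidate k passed the structure checks; reporting the ",
            "best-objective model without structure guarantees")
    forced <- TRUE
    # rank candidates by how close the full set of fitted true clusters
    # comes to the 0.5 centroid-sum rule (comparable across k, unlike the
    # best-subset p, which grows with the number of subsets available)
    full_set_p <- function(res) {
      if (is.null(res) || is.null(res$model)) return(-Inf)
      tt <- subclone_rule_test(F, res$model$Theta,
                               seq_len(res$model$k), config$t_test_alpha)
      if (is.finite(tt$combined_p)) tt$combined_p else -Inf
    }
    ph <- vapply(hard, function(h) full_set_p(h$best_any), numeric(1))
    pf <- vapply(fuzzy, function(fz) full_set_p(fz$best_any), numeric(1))
    ps <- pmax(ph, pf)
    if (all(!is.finite(ps))) stop("no EM run converged for any k",
                                  call. = FALSE)
    chosen_k <- ks[which.max(ps)]
    qf <- which.max(ps)
    hard_best <- if (ph[qf] >= pf[qf]) hard[[qf]]$best_any else
      fuzzy[[qf]]$best_any
    hard_best <- hard_best %||% hard[[qf]]$best_any %||% fuzzy[[qf]]$best_any
    sel <- list(chosen_k = chosen_k, report = tibble::tibble(
      k = integer(), W = numeric(), ref_W_mean = numeric(),
      ref_W_se = numeric(), gap = numeric()))
  }

  q <- match(chosen_k, ks)
  if (is.null(fuzzy[[q]])) {
    fuzzy[[q]] <- fit_mode_k(mats, km$centroids, chosen_k, "fuzzy", config)
  }
  fuzzy_best <- fuzzy[[q]]$best %||% if (forced) fuzzy[[q]]$best_any else NULL

  if (!forced && !hard_ok[q]) {
    # only the fuzzy fit is structure-consistent at this k
    ref_lambda <- (hard_best %||% fuzzy_best)$model$Lambda
    choice <- list(model = fuzzy_best$model, mode = "fuzzy",
                   max_jaccard = pairwise_posterior_jaccard(ref_lambda))
    final <- fuzzy_best
  } else {
    choice <- choose_mode(hard_best$model,
                          if (is.null(fuzzy_best)) NULL else fuzzy_best$model,
                          config$jaccard_threshold)
    final <- if (choice$mode == "fuzzy") fuzzy_best else hard_best
  }

  flags <- label_false_variants(final$model)
  K <- ncol(final$model$Theta)
  labels <- cluster_labels(final$model$k)
  assigned <- labels[max.col(final$model$Theta, ties.method = "first")]
  theta_tb <- tibble::as_tibble(final$model$Theta, .name_repair = "minimal")
  names(theta_tb) <- paste0("theta_", labels)
  membership <- dplyr::bind_cols(
    tibble::tibble(variant_id = variant_ids(table), cluster = assigned,
                   flag = flags),
    theta_tb
  )

  structure(
    list(
      table = table,
      config = config,
      chosen_k = final$model$k,
      mode = choice$mode,
      max_jaccard = choice$max_jaccard,
      model = final$model,
      hard_model = hard_best$model,
      structure = final$structure,
      selection = sel$report,
      feasible_k = ks[feasible],
      membership = membership,
      forced = forced
    ),
    class = "declone_fit"
  )
}

# Best structure-consistent model for one (k, mode): run the EM from
# n_restarts random provisional clone sets (memoized on the selected
# centroid subset - identical subsets give identical deterministic fits),
# keep the accepted model with the highest objective. `best_any` tracks the
# best converged model regardless of the structure checks, for the
# all-infeasible fallback.
fit_mode_k <- function(mats, centroids_T, k, mode, config,
                       restarts = seq_len(config$n_restarts)) {
  cache <- new.env(parent = emptyenv())
  best <- NULL
  best_any <- NULL
  for (r in restarts) {
    selset <- select_initial_clones(centroids_T, k, restart = r,
                                    seed = config$seed)
    key <- paste(selset$indices, collapse = ",")
    res <- cache[[key]]
    if (is.null(res)) {
      res <- run_restart(mats, selset, mode, config)
      cache[[key]] <- res
    }
    if (is.null(res$model)) next
    if (is.null(best_any) || res$model$objective > best_any$model$objective) {
      best_any <- res
    }
    if (!is.null(res$structure) &&
        (is.null(best) || res$model$objective > best$model$objective)) {
      best <- res
    }
  }
  if (!is.null(best_any) && is.null(best_any$structure)) {
    best_any <- forced_structure(best_any, mats, config)
  }
  list(best = best, best_any = best_any)
}

run_restart <- function(mats, selset, mode, config) {
  mu0 <- cbind(selset$tp_centroids, selset$fv_centroid)
  fit <- cpp_run_em(mats$alt, mats$total, mats$F, mu0, mats$p_se,
                    config$fp_prior, config$tn_prior_total, config$c_scale,
                    mode == "hard", config$max_em_iter, config$min_em_iter)
  if (isTRUE(fit$aborted)) return(list(model = NULL, structure = NULL))
  model <- new_clone_model(fit$mu, fit$Lambda, fit$Theta, mode,
                           fit$objective, fit$objective_trace, fit$n_iter,
                           fit$converged,
                           rownames(mats$alt), colnames(mats$alt))
  theta_sum <- if (mode == "fuzzy") {
    assign_membership(model$Lambda, "hard")
  } else {
    model$Theta
  }
  strct <- check_clone_structure(mats$F, model$Theta, config$t_test_alpha,
                                 theta_sum = theta_sum)
  list(model = model, structure = strct)
}

# Attach a best-effort structure to a model that failed the checks: take the
# valid subset with maximal combined p regardless of significance and treat
# every other cluster as ancestral without validated edges.
forced_structure <- function(res, mats, config) {
  if (is.null(res) || is.null(res$model)) return(res)
  stats <- cluster_vaf_stats(mats$F, res$model$Theta)
  all_sub <- subsets_for_k(stats$k)
  tt <- subset_t_tests(stats, all_sub$S, config$t_test_alpha)
  ok <- which(tt$valid)
  if (length(ok) == 0) ok <- seq_along(all_sub$subsets)
  score <- tt$combined_p[ok]
  score[!is.finite(score)] <- -Inf
  best <- ok[which.max(score)]
  if (length(best) == 0) best <- ok[1]
  ind <- all_sub$subsets[[best]]
  res$structure <- structure(
    list(individual = ind,
         ancestral = setdiff(seq_len(stats$k), ind),
         fv_index = ncol(res$model$Theta),
         edges = tibble::tibble(superclone = integer(),
                                subclones = list(), combined_p = numeric()),
         subclone_rule_p = tt$combined_p[best],
         sum_rule_p = numeric(0)),
    class = "clone_structure")
  res
}

#' @export
print.declone_fit <- function(x, ...) {
  cat(sprintf(
    "<declone_fit> %d variants, %d sample(s): k = %d true clone(s) + FV, %s clustering\n",
    nrow(x$table), length(sample_ids(x$table)), x$chosen_k, x$mode))
  cat(sprintf("  individual: %s | ancestral: %s | %d variant(s) flagged FV\n",
              paste0("C", x$structure$individual, collapse = " "),
              if (length(x$structure$ancestral) > 0)
                paste0("C", x$structure$ancestral, collapse = " ") else "-",
              sum(x$membership$flag == "FV")))
  invisible(x)
}

#' Tidy per-variant membership of a decomposition
#'
#' @param x A `declone_fit`.
#' @param ... Unused.
#' @return A tibble with one row per variant: `variant_id`, assigned
#'   `cluster`, TV/FV `flag` and the membership columns `theta_*`.
#' @export
tidy.declone_fit <- function(x, ...) x$membership

#' One-row summary of a decomposition
#'
#' @param x A `declone_fit`.
#' @param ... Unused.
#' @return A one-row tibble: clone number, counts of individual and
#'   ancestral clones, clustering mode, objective, posterior overlap, FV
#'   count and convergence flag.
#' @export
glance.declone_fit <- function(x, ...) {
  tibble::tibble(
    k = x$chosen_k,
    n_individual = length(x$structure$individual),
    n_ancestral = length(x$structure$ancestral),
    mode = x$mode,
    objective = x$model$objective,
    max_jaccard = x$max_jaccard,
    n_fv = sum(x$membership$flag == "FV"),
    converged = x$model$converged,
    forced = x$forced
  )
}

#' Broom-style generics
#'
#' Minimal `tidy()` / `glance()` generics so fitted objects summarize into
#' tibbles without a hard dependency on broom.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a decomposition
#'
#' With two or more samples, a scatter of the first two samples' VAFs
#' colored by assigned cluster (false variants in black); with one sample,
#' VAF against variant rank with the same coloring.
#'
#' @param object A `declone_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.declone_fit <- function(object, ...) {
  F <- compute_vaf(object$table)
  df <- tibble::tibble(
    cluster = object$membership$cluster,
    vaf1 = F[1, ]
  )
  pal_fv <- c(FV = "black")
  if (nrow(F) >= 2) {
    df$vaf2 <- F[2, ]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$vaf1, .data$vaf2,
                                          colour = .data$cluster)) +
      ggplot2::geom_point(alpha = 0.7, size = 1) +
      ggplot2::labs(x = paste0("VAF ", sample_ids(object$table)[1]),
                    y = paste0("VAF ", sample_ids(object$table)[2]))
  } else {
    df$rank <- rank(df$vaf1, ties.method = "first")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$vaf1,
                                          colour = .data$cluster)) +
      ggplot2::geom_point(alpha = 0.7, size = 1) +
      ggplot2::labs(x = "variant rank", y =
                      paste0("VAF ", sample_ids(object$table)[1]))
  }
  p + ggplot2::theme_minimal()
}

#' Write decomposition result files
#'
#' Writes `membership.tsv` (per-variant assignment and memberships),
#' `clones.tsv` (per-cluster centroids and class), `phylogeny.tsv`
#' (superclone edges) and `run.json` (run metadata and the model-selection
#' report) into `out_dir`.
#'
#' @param fit A `declone_fit`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_decomposition <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(fit$membership, file.path(out_dir, "membership.tsv"),
                   progress = FALSE)

  k <- fit$chosen_k
  labels <- cluster_labels(k)
  class_ <- rep("individual", k + 1L)
  class_[fit$structure$ancestral] <- "ancestral"
  class_[k + 1L] <- "FV"
  cent <- t(fit$model$centroids)
  colnames(cent) <- paste0("centroid_", sample_ids(fit$table))
  clones <- dplyr::bind_cols(
    tibble::tibble(cluster = labels, class = class_),
    tibble::as_tibble(cent))
  readr::write_tsv(clones, file.path(out_dir, "clones.tsv"),
                   progress = FALSE)

  edges <- fit$structure$edges
  etab <- if (nrow(edges) == 0) {
    tibble::tibble(superclone = character(), subclone = character(),
                   combined_p = numeric())
  } else {
    tidyr::unnest(
      tibble::tibble(superclone = paste0("C", edges$superclone),
                     subclone = lapply(edges$subclones,
                                       function(s) paste0("C", s)),
                     combined_p = edges$combined_p),
      "subclone")
  }
  readr::write_tsv(etab, file.path(out_dir, "phylogeny.tsv"),
                   progress = FALSE)

  meta <- list(
    k = fit$chosen_k, mode = fit$mode, objective = fit$model$objective,
    max_jaccard = fit$max_jaccard, seed = fit$config$seed,
    feasible_k = fit$feasible_k, forced = fit$forced,
    selection = fit$selection
  )
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
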