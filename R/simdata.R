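#' Simulation configuration
#'
#' Parameters of the synthetic benchmark generator. Defaults reproduce the
#' reference benchmark conditions: 500 variants at mean depth 125 (SD 8,
#' emulating 125x sequencing), base quality 20 for every variant, and two
#' clone-proportion regimes - `"decoy"` draws Dirichlet shapes
#' `Binomial(10y, 0.5)` per clone `y` (systematically unequal, dispersed
#' proportions) while `"lump"` draws every shape from `Binomial(10k, 0.5)`
#' (agglomerated, near-equal proportions).
#'
#' @param k Number of true clones.
#' @param m Number of samples.
#' @param n Total number of variants, false variants included.
#' @param mean_depth,depth_sd Normal read-depth model (rounded, floored at
#'   1 read).
#' @param fv_fraction Fraction of the `n` variants that are false variants.
#' @param regime `"decoy"` or `"lump"`.
#' @param bq Phred base quality written for every variant.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k, m = 1L, n = 500L, mean_depth = 125,
                       depth_sd = 8, fv_fraction = 0,
                       regime = c("decoy", "lump"), bq = 20L, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(k >= 1, m >= 1, n >= k, mean_depth > 0, depth_sd >= 0,
            fv_fraction >= 0, fv_fraction < 1)
  structure(
    list(k = as.integer(k), m = as.integer(m), n = as.integer(n),
         mean_depth = mean_depth, depth_sd = depth_sd,
         fv_fraction = fv_fraction, regime = regime, bq = bq,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw clone proportions
#'
#' Per sample, Dirichlet-distributed clone proportions with binomially
#' sampled shape parameters: `Binomial(10y, 0.5)` for clone `y` in the
#' decoy regime, `Binomial(10k, 0.5)` for every clone in the lump regime.
#' Shapes are floored at 1 so the Dirichlet never degenerates.
#'
#' @param k Number of clones.
#' @param m Number of samples.
#' @param regime `"decoy"` or `"lump"`.
#' @param seed Integer seed.
#' @return `m x k` matrix of proportions; rows sum to 1.
#' @export
sample_clone_proportions <- function(k, m = 1L, regime = c("decoy", "lump"),
                                     seed = 1L) {
  regime <- match.arg(regime)
  set.seed(derive_seed(seed, 23L))
  rho <- matrix(0, m, k)
  for (i in seq_len(m)) {
    shape <- if (regime == "decoy") {
      rbinom(k, 10L * seq_len(k), 0.5)
    } else {
      rbinom(k, 10L * k, 0.5)
    }
    shape <- pmax(shape, 1)
    g <- rgamma(k, shape = shape, rate = 1)
    rho[i, ] <- g / sum(g)
  }
  rho
}

#' Reverse-sigmoid false-variant VAF density
#'
#' Unnormalized density of false-variant VAFs,
#' `1 / (1 + exp(100 f - 5))`, a reverse sigmoid concentrating mass below
#' VAF 0.05 the way sequencing artifacts do.
#'
#' @param f VAF values in `[0, 1]`.
#' @return Unnormalized density values.
#' @export
fv_vaf_density <- function(f) 1 / (1 + exp(100 * f - 5))

#' Mean and median of the false-variant VAF model
#'
#' Numerical quadrature of the normalized reverse-sigmoid density on a
#' uniform grid over `[0, 1]` (trapezoid rule; CDF inverted for the
#' median).
#'
#' @param step Grid step (default 1e-4).
#' @return A list with `mean`, `median` and the grid size `n_grid`.
#' @export
fv_vaf_moments <- function(step = 1e-4) {
  f <- seq(0, 1, by = step)
  d <- fv_vaf_density(f)
  w <- step * (d[-1] + d[-length(d)]) / 2 # trapezoid panel masses
  Z <- sum(w)
  cdf <- cumsum(w) / Z
  mids <- (f[-1] + f[-length(f)]) / 2
  list(
    mean = sum(mids * w) / Z,
    median = mids[which(cdf >= 0.5)[1]],
    n_grid = length(f)
  )
}

#' Sample false-variant VAFs
#'
#' Inverse-CDF draws from the normalized reverse-sigmoid density on a fine
#' grid. False calls are sequencing artifacts, so each sample of a
#' multi-sample dataset receives an independent draw per variant.
#'
#' @param count Number of draws.
#' @param step Grid step for the inverse CDF (default 1e-4).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Numeric vector of `count` VAFs.
#' @export
sample_false_variant_vafs <- function(count, step = 1e-4, seed = NULL) {
  if (count == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(derive_seed(seed, 31L))
  f <- seq(0, 1, by = step)
  d <- fv_vaf_density(f)
  w <- step * (d[-1] + d[-length(d)]) / 2
  cdf <- c(0, cumsum(w) / sum(w))
  u <- runif(count)
  approx(cdf, f, xout = u, ties = "ordered", rule = 2)$y
}

#' Simulate read counts for a given ground truth
#'
#' True variants are allocated to clones by a uniform multinomial; per
#' variant and sample the total depth is `round(Normal(mean_depth,
#' depth_sd))` floored at one read and the alternate count is
#' `Binomial(total, rho/2)` - heterozygous diploid variants, so the
#' expected VAF is half the clone proportion. False variants draw an
#' independent reverse-sigmoid VAF per sample and realize
#' `Binomial(total, f)` alternate reads.
#'
#' @param proportions `m x k` clone-proportion matrix.
#' @param config A [sim_config()].
#' @return A list with `table` (a [variant_table]) and `truth` (a tibble
#'   with `variant_id` and `clone`, the clone label or `"FV"`).
#' @export
simulate_variant_counts <- function(proportions, config) {
  set.seed(derive_seed(config$seed, 47L))
  k <- config$k
  m <- config$m
  n <- config$n
  n_fv <- as.integer(round(n * config$fv_fraction))
  n_tv <- n - n_fv
  alloc <- as.integer(rmultinom(1, n_tv, rep(1 / k, k)))
  clone_of <- c(rep(seq_len(k), alloc), rep(NA_integer_, n_fv))

  total <- matrix(pmax(1L, as.integer(round(rnorm(m * n, config$mean_depth,
                                                  config$depth_sd)))),
                  m, n)
  alt <- matrix(0L, m, n)
  for (i in seq_len(m)) {
    for (y in seq_len(k)) {
      sel <- which(clone_of == y)
      if (length(sel) == 0) next
      alt[i, sel] <- rbinom(length(sel), total[i, sel],
                            proportions[i, y] / 2)
    }
  }
  if (n_fv > 0) {
    sel <- which(is.na(clone_of))
    for (i in seq_len(m)) {
      fvs <- sample_false_variant_vafs(n_fv)
      alt[i, sel] <- rbinom(n_fv, total[i, sel], fvs)
    }
  }

  pos <- sample.int(2^28, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  altb <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tb <- tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = pos, ref = ref, alt = unname(altb), bq = config$bq
  )
  ids <- paste0("s", seq_len(m))
  for (i in seq_len(m)) {
    tb[[paste0(ids[i], "_total")]] <- total[i, ]
    tb[[paste0(ids[i], "_alt")]] <- alt[i, ]
  }
  table <- variant_table(tb)
  truth <- tibble::tibble(
    variant_id = variant_ids(table),
    clone = ifelse(is.na(clone_of), "FV", paste0("C", clone_of))
  )
  list(table = table, truth = truth)
}

#' Generate a complete simulated benchmark dataset
#'
#' Composes [sample_clone_proportions()] and [simulate_variant_counts()]
#' into one seeded dataset with ground truth. Expected per-clone VAFs are
#' half the clone proportions.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `table` (a [variant_table]),
#'   `truth` (tibble of per-variant clone labels), `proportions` (`m x k`),
#'   `expected_vafs` (`m x k`) and `config`.
#' @export
#' @examples
#' sim <- generate_sim_dataset(sim_config(k = 3, m = 2, n = 300, seed = 11))
#' head(sim$truth)
generate_sim_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rho <- sample_clone_proportions(config$k, config$m, config$regime,
                                  config$seed)
  sim <- simulate_variant_counts(rho, config)
  structure(
    list(table = sim$table, truth = sim$truth, proportions = rho,
         expected_vafs = rho / 2, config = config),
    class = "sim_dataset"
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the variant TSV (readable by [read_variant_table()]) and a
#' `truth.tsv` with the per-variant clone labels.
#'
#' @param sim A `sim_dataset` from [generate_sim_dataset()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(sim$table, file.path(out_dir, "variants.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
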