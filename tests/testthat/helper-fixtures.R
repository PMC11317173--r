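# Shared fixtures, all generated in code.

# A small well-formed wide-TSV variant table as a tibble.
make_count_tibble <- function(m = 2, n = 6, seed = 1) {
  set.seed(seed)
  tb <- tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("T", n), bq = 20
  )
  for (i in seq_len(m)) {
    total <- as.integer(round(rnorm(n, 125, 8)))
    tb[[paste0("s", i, "_total")]] <- total
    tb[[paste0("s", i, "_alt")]] <- as.integer(rbinom(n, total, 0.2))
  }
  tb
}

# Single-sample table with two tight VAF clusters at given centers.
make_two_clone_table <- function(n_per = 60, centers = c(0.1, 0.4),
                                 depth = 125, seed = 1) {
  set.seed(seed)
  n <- n_per * length(centers)
  total <- as.integer(round(rnorm(n, depth, 8)))
  p <- rep(centers, each = n_per)
  alt_reads <- as.integer(rbinom(n, total, p))
  variant_table(tibble::tibble(
    chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "T", bq = 20,
    s1_total = total, s1_alt = alt_reads
  ))
}

# Membership matrix with one-hot assignment by true block structure.
onehot_theta <- function(labels, K) {
  Theta <- matrix(0, length(labels), K)
  Theta[cbind(seq_along(labels), labels)] <- 1
  Theta
}

# Tight VAF matrix (m = 1) with clusters at the given means and spread.
make_cluster_vafs <- function(means, n_per = 100, sd = 0.005, seed = 1) {
  set.seed(seed)
  f <- unlist(lapply(means, function(mu) rnorm(n_per, mu, sd)))
  f <- pmin(pmax(f, 0), 1)
  F <- matrix(f, nrow = 1)
  labels <- rep(seq_along(means), each = n_per)
  list(F = F, Theta = onehot_theta(labels, length(means) + 1L),
       labels = labels)
}

# Brute-force maximum injection weight by explicit enumeration (oracle for
# the assignment DP), valid for min(dim) <= 6.
brute_force_injection <- function(u) {
  transposed <- nrow(u) > ncol(u)
  if (transposed) u <- t(u)
  nr <- nrow(u)
  nc <- ncol(u)
  stopifnot(nr <= 6)
  best <- -Inf
  cols <- seq_len(nc)
  rec <- function(r, avail, w) {
    if (r > nr) {
      best <<- max(best, w)
      return(invisible(NULL))
    }
    for (cc in avail) rec(r + 1L, setdiff(avail, cc), w + u[r, cc])
  }
  rec(1L, cols, 0)
  best
}
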