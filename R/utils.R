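# Internal numerical helpers. Hot paths live in src/em.cpp; these are the
# plain-R counterparts used at test scale and in non-critical code.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix of log-weights.
row_softmax <- function(L) {
  mx <- apply(L, 1L, max)
  W <- exp(L - mx)
  sw <- rowSums(W)
  bad <- !is.finite(mx) | sw == 0
  if (any(bad)) W[bad, ] <- 1 # uniform fallback when everything underflows
  W / rowSums(W)
}

# Deterministic sub-seed derivation: a small LCG over the master seed and a
# sequence of integer offsets, kept inside the 32-bit range R requires.
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483629
  for (o in c(...)) {
    s <- (s * 69069 + as.double(o) + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

cluster_labels <- function(k, fv = TRUE) {
  c(paste0("C", seq_len(k)), if (fv) "FV")
}
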