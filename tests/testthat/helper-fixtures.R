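# Shared fixtures and independent oracles, all built in code.

# The canonical 16-entry 2-mer vocabulary used in the worked tokenization
# example ('gg' = 1, 'cc' = 2, ..., 'ta' = 16).
reference_dimer_vocab <- function() {
  vocabulary_from_map(c("gg", "cc", "gc", "ct", "tg", "ag", "ca", "tc",
                        "ga", "tt", "aa", "gt", "ac", "cg", "at", "ta"))
}

random_dna <- function(n, len, seed = NULL) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Small tokenized two-class fixture for backbone tests.
tiny_tokenized <- function(n_per_class = 40, seq_length = 30, seed = 7,
                           insertion_prob = 0.9) {
  d <- generate_synthetic(synthetic_config(n_per_class = n_per_class,
                                           seq_length = seq_length,
                                           insertion_prob = insertion_prob,
                                           seed = seed))
  v <- build_vocabulary(d, kmer_config(2))
  encode_dataset(d, v)
}

# Exact probability that a fixed motif occurs at least once in `len` i.i.d.
# uniform bases, by dynamic programming over the KMP failure automaton.
# Independent of the generator: used as the scan oracle for background
# motif hits.
motif_hit_prob <- function(motif, len, base_prob = rep(0.25, 4)) {
  m <- strsplit(toupper(motif), "")[[1]]
  k <- length(m)
  alphabet <- c("A", "C", "G", "T")
  # KMP failure links
  fail <- integer(k)
  for (i in seq_len(k - 1)) {
    j <- fail[i]
    while (j > 0 && m[i + 1] != m[j + 1]) j <- fail[j]
    fail[i + 1] <- if (m[i + 1] == m[j + 1]) j + 1 else 0
  }
  # transition[state + 1, base]: next automaton state
  trans <- matrix(0L, k + 1, 4)
  for (s in 0:k) {
    for (a in 1:4) {
      if (s == k) { trans[s + 1, a] <- k; next }  # absorbing: motif found
      j <- s
      while (j > 0 && alphabet[a] != m[j + 1]) j <- fail[j]
      trans[s + 1, a] <- if (alphabet[a] == m[j + 1]) j + 1 else 0
    }
  }
  p <- numeric(k + 1)
  p[1] <- 1
  for (pos in seq_len(len)) {
    q <- numeric(k + 1)
    for (s in 0:k) {
      if (p[s + 1] == 0) next
      for (a in 1:4) {
        q[trans[s + 1, a] + 1] <- q[trans[s + 1, a] + 1] +
          p[s + 1] * base_prob[a]
      }
    }
    p <- q
  }
  p[k + 1]
}

# Exhaustive 2-partition optimum for small point sets: minimal total
# within-cluster sum of squares over every assignment into two non-empty
# clusters.
brute_force_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 1
    grp <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    sse <- 0
    for (g in 1:2) {
      pts <- X[grp == g, , drop = FALSE]
      if (nrow(pts) == 0) { sse <- Inf; break }
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Iterate the single-cell GRU step over a token row: the reference route
# for checking the batched compiled forward pass.
gru_reference_final_state <- function(params_flat, emb, tokens_row, len) {
  H <- ncol(params_flat$Uc_f)
  p <- gru_params(W_z = params_flat$W_f[, 1:H, drop = FALSE],
                  V_z = params_flat$Uzr_f[, 1:H, drop = FALSE],
                  b_z = params_flat$b_f[1:H],
                  W_r = params_flat$W_f[, (H + 1):(2 * H), drop = FALSE],
                  V_r = params_flat$Uzr_f[, (H + 1):(2 * H), drop = FALSE],
                  b_r = params_flat$b_f[(H + 1):(2 * H)],
                  W_C = params_flat$W_f[, (2 * H + 1):(3 * H), drop = FALSE],
                  V_C = params_flat$Uc_f,
                  b_C = params_flat$b_f[(2 * H + 1):(3 * H)])
  h <- numeric(H)
  for (t in seq_len(len)) {
    x <- emb[tokens_row[t] + 1L, ]
    h <- gru_cell_step(x, h, p)$h_t
  }
  h
}
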