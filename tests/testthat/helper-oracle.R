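# Independent, deliberately plain implementations used as oracles.

# Dense affinity propagation coded directly from the message-passing
# equations with explicit loops (no shared code with the package).
dense_ap_oracle <- function(S, preference, maxits = 1000, convits = 15,
                            damping = 0.8) {
  n <- nrow(S)
  diag(S) <- preference
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  e_prev <- rep(NA, n)
  stable <- 0
  for (iter in seq_len(maxits)) {
    Rnew <- matrix(0, n, n)
    for (i in 1:n) {
      as_row <- A[i, ] + S[i, ]
      for (k in 1:n) {
        Rnew[i, k] <- S[i, k] - max(as_row[-k])
      }
    }
    R <- damping * R + (1 - damping) * Rnew
    Anew <- matrix(0, n, n)
    for (k in 1:n) {
      rp <- pmax(R[, k], 0)
      rp[k] <- R[k, k]
      total <- sum(rp)
      for (i in 1:n) {
        if (i == k) Anew[k, k] <- total - rp[k]
        else Anew[i, k] <- min(0, total - rp[i])
      }
    }
    A <- damping * A + (1 - damping) * Anew
    e <- (diag(A) + diag(R)) > 0
    stable <- if (identical(e, e_prev)) stable + 1 else 0
    e_prev <- e
    if (stable >= convits && any(e)) break
  }
  ex <- which((diag(A) + diag(R)) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  assign <- integer(n)
  for (i in 1:n) {
    if (i %in% ex) assign[i] <- i
    else assign[i] <- ex[which.max(S[i, ex])]
  }
  match(assign, sort(unique(assign)))
}

# Canonical k-mer counting by direct string chopping and per-window
# canonicalization (oracle for count_kmers).
brute_count_oracle <- function(sequence, k, features) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  counts <- setNames(integer(length(features)), features)
  for (start in seq_len(nchar(sequence) - k + 1)) {
    w <- substr(sequence, start, start + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    canon <- min(w, rc1(w))
    if (canon %in% features) counts[canon] <- counts[canon] + 1L
  }
  counts
}

# Trustworthiness of an embedding (rank-based neighborhood preservation),
# computed from first principles.
trustworthiness_oracle <- function(X, Y, k = 12) {
  n <- nrow(X)
  dx <- as.matrix(dist(X)); diag(dx) <- Inf
  dy <- as.matrix(dist(Y)); diag(dy) <- Inf
  total <- 0
  for (i in 1:n) {
    rank_x <- rank(dx[i, ], ties.method = "first")
    nn_y <- order(dy[i, ])[1:k]
    for (j in nn_y) total <- total + max(0, rank_x[j] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}
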