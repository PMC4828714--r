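#' Embed contig features in two dimensions by t-SNE
#'
#' Reduces the CLR feature matrix to 2-D coordinates with t-distributed
#' stochastic neighbor embedding, the standard formulation: per-point
#' Gaussian bandwidths are calibrated by binary search to a fixed
#' perplexity, the joint neighbor distribution is symmetrized, and the
#' Kullback-Leibler divergence to the Student-t low-dimensional
#' distribution is minimized by momentum gradient descent with adaptive
#' per-coordinate gains, early exaggeration, and the reference default
#' learning schedule (exaggeration 12 for the first 250 iterations,
#' momentum 0.5 switching to 0.8 at iteration 250, learning rate 200).
#'
#' Gradients are computed exactly (all pairwise interactions); `theta` is
#' recorded for provenance and a Barnes-Hut approximation is not applied,
#' which at the problem sizes this package targets (up to a few thousand
#' contigs in stage 1) is both affordable and more accurate. No PCA
#' preprocessing is performed. The embedding is stochastic; `seed` pins
#' the random initialization and makes runs reproducible.
#'
#' When `n < 3 * perplexity + 1` the perplexity is lowered to
#' `floor((n - 1) / 3)` with a warning.
#'
#' @param features Numeric matrix, one row per contig (e.g. from
#'   [contig_features()]).
#' @param perplexity Target perplexity (effective neighborhood size),
#'   default 20.
#' @param theta Barnes-Hut accuracy parameter, recorded in the result;
#'   gradients are exact regardless (default 0.5).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Number of gradient iterations (default 1000).
#' @param eta Learning rate (default 200).
#' @param exaggeration Early-exaggeration factor (default 12).
#' @param stop_lying_iter Iteration at which exaggeration is removed
#'   (default 250).
#' @param mom_switch_iter Iteration at which momentum switches from 0.5 to
#'   0.8 (default 250).
#' @param cost_every Record the KL divergence every this many iterations
#'   (default 50).
#' @param verbose Print progress.
#' @return A list of class `tsne_embedding`: `coords` (n x 2 matrix, row
#'   names preserved), `costs` (data frame of checkpoint iteration and KL
#'   divergence), and `params`.
#' @export
embed_tsne <- function(features, perplexity = 20, theta = 0.5, seed = 42,
                       max_iter = 1000, eta = 200, exaggeration = 12,
                       stop_lying_iter = 250, mom_switch_iter = 250,
                       cost_every = 50, verbose = FALSE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 4L) stop("too few points to embed (need at least 4, got ", n, ")")
  if (n < 3 * perplexity + 1) {
    perplexity <- floor((n - 1) / 3)
    warning("perplexity too large for ", n, " points; lowered to ", perplexity)
  }
  p <- tsne_affinities(x, perplexity)
  y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L))

  gains <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  momentum <- 0.5
  pe <- p * exaggeration
  costs <- data.frame(iter = integer(0), cost = numeric(0))

  for (iter in seq_len(max_iter)) {
    if (iter == stop_lying_iter + 1L) pe <- p
    if (iter == mom_switch_iter + 1L) momentum <- 0.8

    ss <- rowSums(y^2)
    num <- 1 / (1 + outer(ss, ss, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    z <- sum(num)
    w <- (pe - num / z) * num      # (P - Q) * student-t kernel
    grad <- 4 * (y * rowSums(w) - w %*% y)

    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))

    if (iter %% cost_every == 0L || iter == max_iter) {
      q <- pmax(num / z, 1e-12)
      kl <- sum(p * log(pmax(p, 1e-12) / q))
      costs <- rbind(costs, data.frame(iter = iter, cost = kl))
      if (verbose) message("t-SNE iteration ", iter, ": KL = ", signif(kl, 6))
    }
  }
  rownames(y) <- rownames(x)
  colnames(y) <- c("x", "y")
  structure(
    list(coords = y, costs = costs,
         params = list(perplexity = perplexity, theta = theta, pca = FALSE,
                       seed = seed, max_iter = max_iter, eta = eta,
                       exaggeration = exaggeration)),
    class = "tsne_embedding"
  )
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat("t-SNE embedding: ", nrow(x$coords), " points, perplexity ",
      x$params$perplexity, ", final KL ",
      signif(utils::tail(x$costs$cost, 1L), 4), "\n", sep = "")
  invisible(x)
}

# Symmetrized joint neighbor probabilities at a fixed perplexity.
# Per-row Gaussian precisions (beta) are found by binary search so that
# the Shannon entropy of the conditional distribution equals
# log(perplexity).
tsne_affinities <- function(x, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(x)
  ss <- rowSums(x^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (try in seq_len(max_tries)) {
      pij <- exp(-di * beta)
      sp <- sum(pij)
      if (sp == 0) { h <- 0; pij[] <- 0 }
      else {
        h <- log(sp) + beta * sum(di * pij) / sp
        pij <- pij / sp
      }
      if (abs(h - target) < tol) break
      if (h > target) {         # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- pij
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}
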