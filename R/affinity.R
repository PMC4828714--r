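#' Sparse negative-squared-distance similarity matrix
#'
#' Builds the affinity-propagation input from 2-D embedding coordinates:
#' the similarity between two points is the negative squared Euclidean
#' distance, and pairs whose squared distance is at or beyond `threshold`
#' are disconnected (encoded as `-Inf`), so the similarity graph may fall
#' apart into connected components that are then clustered independently.
#' The diagonal is left as `NA`; [affinity_propagation()] fills it with
#' the preference.
#'
#' @param coords Numeric matrix of point coordinates (rows = points),
#'   typically the 2-D embedding.
#' @param threshold Squared-distance cutoff (default 500). `Inf` yields a
#'   complete graph, identical to dense affinity propagation input.
#' @return An n x n similarity matrix with `-Inf` for removed pairs and
#'   `NA` on the diagonal.
#' @export
sparse_similarity <- function(coords, threshold = 500) {
  x <- as.matrix(coords)
  if (!all(is.finite(x))) stop("coordinates must be finite")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  ss <- rowSums(x^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  s <- -d2
  s[d2 >= threshold] <- -Inf
  diag(s) <- NA_real_
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by the responsibility/availability message
#' passing of Frey & Dueck, run on a (possibly sparsified) similarity
#' matrix. Messages are damped, the algorithm stops when the exemplar set
#' has been stable for `convits` consecutive sweeps or after `maxits`
#' sweeps, and every point is then assigned to the reachable exemplar of
#' maximal similarity (ties broken by lowest point index; points with no
#' reachable exemplar become singletons). `-Inf` similarities are never
#' traversed, so disconnected components of the similarity graph are
#' clustered independently; fully isolated points are returned as
#' singleton clusters.
#'
#' @param s Similarity matrix from [sparse_similarity()] (diagonal `NA` or
#'   ignored; `-Inf` marks absent edges).
#' @param preference Shared exemplar preference placed on the diagonal:
#'   a number, or `"median"` (default) for the median of the finite
#'   off-diagonal similarities. Higher preferences yield more exemplars.
#' @param maxits Maximum number of message-passing sweeps (default 1000).
#' @param convits Sweeps of unchanged exemplar decisions required for
#'   convergence (default 15).
#' @param damping Damping factor in `[0.5, 1)` applied to message updates
#'   (default 0.8).
#' @return A list of class `ap_result`: `labels` (integer cluster per
#'   point, numbered 1..K in order of exemplar index), `exemplars`
#'   (point index of each cluster's exemplar), `converged`, `iterations`,
#'   `preference`.
#' @export
affinity_propagation <- function(s, preference = "median", maxits = 1000,
                                 convits = 15, damping = 0.8) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n == 0L) stop("empty similarity matrix")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (convits >= maxits) stop("convits must be smaller than maxits")
  off <- s; diag(off) <- NA_real_
  fin <- off[is.finite(off)]
  pref <- if (identical(preference, "median")) {
    if (length(fin) == 0L) -1 else stats::median(fin)
  } else as.numeric(preference)

  # Isolated points (no finite off-diagonal similarity) would produce
  # infinite self-responsibilities; they are singletons by construction.
  deg <- rowSums(is.finite(off))
  iso <- which(deg == 0L)
  active <- setdiff(seq_len(n), iso)

  labels <- integer(n)
  exemplars <- integer(0)
  converged <- TRUE
  iterations <- 0L

  if (length(active) > 0L) {
    sa <- off[active, active, drop = FALSE]
    diag(sa) <- pref
    core <- ap_core(sa, maxits, convits, damping)
    converged <- core$converged
    iterations <- core$iterations
    ex_local <- core$exemplars
    # Assign each point to the reachable exemplar of maximal similarity;
    # ties go to the lowest exemplar index, exemplars map to themselves.
    m <- length(active)
    assign_to <- integer(m)
    for (i in seq_len(m)) {
      if (i %in% ex_local) { assign_to[i] <- i; next }
      si <- sa[i, ex_local]
      if (all(!is.finite(si))) {           # unreachable: becomes a singleton
        ex_local <- sort(c(ex_local, i))
        assign_to[i] <- i
      } else {
        assign_to[i] <- ex_local[which.max(si)]
      }
    }
    all_ex <- sort(unique(c(active[ex_local], iso)))
    labels[active] <- match(active[assign_to], all_ex)
    labels[iso] <- match(iso, all_ex)
    exemplars <- all_ex
  } else {
    exemplars <- iso
    labels[iso] <- seq_along(iso)
  }
  if (!converged)
    warning("affinity propagation did not converge within ", maxits,
            " iterations; returning current assignment")
  structure(
    list(labels = stats::setNames(labels, rownames(s)),
         exemplars = exemplars, converged = converged,
         iterations = iterations, preference = pref),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat("affinity propagation: ", length(x$exemplars), " clusters over ",
      length(x$labels), " points (",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " sweeps, preference ",
      signif(x$preference, 4), ")\n", sep = "")
  invisible(x)
}

# The message-passing core: standard responsibility/availability updates
# with damping, on a similarity matrix whose diagonal already holds the
# preference and whose absent edges are -Inf. Every row is assumed to have
# at least one finite off-diagonal entry.
ap_core <- function(s, maxits, convits, damping) {
  n <- nrow(s)
  idx <- seq_len(n)
  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  e_prev <- rep(NA, n)
  stable <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < maxits) {
    iter <- iter + 1L

    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    as_ <- a + s
    i1 <- max.col(as_, ties.method = "first")
    first <- as_[cbind(idx, i1)]
    as_[cbind(idx, i1)] <- -Inf
    second <- as_[cbind(idx, max.col(as_, ties.method = "first"))]
    rnew <- s - first
    rnew[cbind(idx, i1)] <- s[cbind(idx, i1)] - second
    r <- damping * r + (1 - damping) * rnew

    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' != i,k} max(0, r(i',k)))
    #                 a(k,k) = sum_{i' != k} max(0, r(i',k))
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    anew <- rep(colSums(rp), each = n) - rp
    da <- diag(anew)
    anew <- pmin(anew, 0)
    diag(anew) <- da
    a <- damping * a + (1 - damping) * anew

    e <- (diag(a) + diag(r)) > 0
    if (identical(e, e_prev)) stable <- stable + 1L else stable <- 0L
    e_prev <- e
    if (stable >= convits && any(e)) { converged <- TRUE; break }
  }
  ex <- which((diag(a) + diag(r)) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(a) + diag(r))
  list(exemplars = ex, converged = converged, iterations = iter)
}
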