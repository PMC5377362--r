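# Internal k-means engine for patch dictionaries.
#
# Not a general-purpose replacement for stats::kmeans: it exists because the
# dictionary contract requires (a) k-means++ seeding, (b) deterministic
# best-of-n restarts under one seed, and (c) an empty-cluster policy that
# re-seeds a dead center at the point farthest from it instead of failing,
# so the paired DF atom for every MR atom is always defined. Assignment uses
# the expansion |x - c|^2 = |x|^2 + |c|^2 - 2 x.c with BLAS matrix products,
# chunked over rows to bound memory.

# nearest center index and squared distance for each row of X; works on the
# similarity 2 x.c - |c|^2 so the argmax needs one dgemm and one sweep per
# chunk (|x - c|^2 = |x|^2 - that similarity)
.assign_to_centers <- function(X, centers, x_sq = NULL, chunk = 4e6) {
  n <- nrow(X); k <- nrow(centers)
  if (is.null(x_sq)) x_sq <- rowSums(X^2)
  c_sq <- rowSums(centers^2)
  rows_per_chunk <- max(1L, as.integer(chunk / k))
  assign_idx <- integer(n)
  dist_sq <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + rows_per_chunk - 1L)
    S <- tcrossprod(X[start:end, , drop = FALSE], centers) # (end-start+1) x k
    S <- sweep(2 * S, 2L, c_sq, "-")
    j <- max.col(S, ties.method = "first")
    assign_idx[start:end] <- j
    dist_sq[start:end] <- x_sq[start:end] - S[cbind(seq_len(end - start + 1L), j)]
    start <- end + 1L
  }
  list(assignment = assign_idx, dist_sq = pmax(dist_sq, 0))
}

# k-means++ seeding: D^2-weighted sequential center choice
.kmeanspp_init <- function(X, k, x_sq = rowSums(X^2)) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (k == 1L) return(centers)
  dist_to <- function(cvec) { # |x - c|^2 via gemv, clamped at 0
    pmax(x_sq + sum(cvec^2) - 2 * as.numeric(X %*% cvec), 0)
  }
  dmin <- dist_to(centers[1L, ])
  for (j in 2L:k) {
    tot <- sum(dmin)
    idx <- if (tot <= 0) sample.int(n, 1L) else { # all remaining points duplicate a center
      sample.int(n, 1L, prob = dmin / tot)
    }
    centers[j, ] <- X[idx, ]
    dmin <- pmin(dmin, dist_to(centers[j, ]))
  }
  centers
}

# One Lloyd run from given centers. Stops at an exact fixed point (the
# assignment stops changing, so every center is precisely the mean of its
# members); once the relative inertia improvement drops below `tol`, at most
# `polish` further iterations are allowed to reach that fixed point.
.lloyd <- function(X, centers, max_iter, tol, x_sq,
                   polish = if (nrow(X) <= 5000L) 20L else 2L) {
  k <- nrow(centers)
  inertia_prev <- Inf
  tol_hits <- 0L
  prev_assign <- NULL
  a <- NULL
  for (iter in seq_len(max_iter)) {
    a <- .assign_to_centers(X, centers, x_sq)
    # empty-cluster policy: re-seed at the point farthest from the dead center
    for (pass in seq_len(5L)) {
      counts <- tabulate(a$assignment, nbins = k)
      empties <- which(counts == 0L)
      if (length(empties) == 0L) break
      for (j in empties) {
        dj <- x_sq + sum(centers[j, ]^2) - 2 * as.numeric(X %*% centers[j, ])
        centers[j, ] <- X[which.max(dj), ]
      }
      a <- .assign_to_centers(X, centers, x_sq)
    }
    counts <- tabulate(a$assignment, nbins = k)
    if (any(counts == 0L)) { # still empty after re-seeding: force-assign nearest point
      for (j in which(counts == 0L)) {
        dj <- x_sq + sum(centers[j, ]^2) - 2 * as.numeric(X %*% centers[j, ])
        a$assignment[which.min(dj)] <- j
      }
      counts <- tabulate(a$assignment, nbins = k)
    }
    if (identical(a$assignment, prev_assign)) break # exact Lloyd fixed point
    sums <- rowsum(X, a$assignment, reorder = FALSE)
    grp <- as.integer(rownames(sums))
    centers[grp, ] <- sums / counts[grp]
    inertia <- sum(a$dist_sq)
    if (is.finite(inertia_prev) &&
        abs(inertia_prev - inertia) <= tol * max(inertia_prev, .Machine$double.eps)) {
      tol_hits <- tol_hits + 1L
      if (tol_hits > polish) break
    }
    prev_assign <- a$assignment
    inertia_prev <- inertia
  }
  a <- .assign_to_centers(X, centers, x_sq) # final consistent assignment
  list(centers = centers, assignment = a$assignment,
       inertia = sum(a$dist_sq), iterations = iter)
}

.patch_kmeans <- function(X, k, seed, n_restarts = 3L, max_iter = 300L, tol = 1e-4) {
  stopifnot(is.matrix(X), k >= 1L, k <= nrow(X))
  x_sq <- rowSums(X^2)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- .kmeanspp_init(X, k, x_sq)
      fit <- .lloyd(X, init, max_iter = max_iter, tol = tol, x_sq = x_sq)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best$n_restarts <- n_restarts
    best
  })
}
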