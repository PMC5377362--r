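# Patch-pair sampling and the paired MR/DF dictionary.
#
# Patches are cubes of odd edge s vectorized in R's native column-major
# (first-axis-fastest) order; the one fixed convention is that MR and DF
# patches from the same center use the same ordering everywhere.

# valid patch centers along one axis: within [lo, hi] and with the full
# patch inside [1, n]; optionally clamped so coverage reaches the roi edge
.axis_centers <- function(lo, hi, n, half, stride, inside_roi) {
  if (inside_roi) {
    lo_c <- lo + half
    hi_c <- hi - half
  } else {
    lo_c <- max(lo, 1L + half)
    hi_c <- min(hi, n - half)
  }
  if (lo_c > hi_c) return(integer(0))
  cs <- seq.int(lo_c, hi_c, by = stride)
  if (inside_roi && cs[length(cs)] != hi_c) cs <- c(cs, hi_c) # clamped final center
  as.integer(cs)
}

# linear-index offsets of a patch footprint relative to its center voxel
.patch_offsets <- function(patch_edge, dims) {
  half <- patch_edge %/% 2L
  rng <- -half:half
  as.vector(outer(outer(rng, rng * dims[1L], "+"), rng * dims[1L] * dims[2L], "+"))
}

# extract vectorized patches at the given centers (matrix n_centers x s^3)
.extract_patches <- function(data, centers, patch_edge) {
  dims <- dim(data)
  off <- .patch_offsets(patch_edge, dims)
  base <- centers[, 1L] + (centers[, 2L] - 1L) * dims[1L] +
    (centers[, 3L] - 1L) * dims[1L] * dims[2L]
  matrix(data[outer(base, off, "+")], nrow = length(base))
}

# cartesian grid of patch centers (n x 3 integer matrix)
.patch_centers <- function(dims, roi, patch_edge, stride, inside_roi) {
  half <- patch_edge %/% 2L
  ax <- lapply(1:3, function(a) {
    .axis_centers(roi$lower[a], roi$upper[a], dims[a], half, stride, inside_roi)
  })
  if (any(lengths(ax) == 0L)) return(matrix(integer(0), 0L, 3L))
  g <- expand.grid(ax[[1L]], ax[[2L]], ax[[3L]], KEEP.OUT.ATTRS = FALSE)
  matrix(c(g[[1L]], g[[2L]], g[[3L]]), ncol = 3L)
}

#' Sample aligned MR/DF patch pairs
#'
#' Extracts one training pair per center voxel on a stride grid inside the
#' ROI; a center is kept when its full patch fits inside the volume. The MR
#' and DF patches at a center use identical vectorization, which is what
#' makes coefficient transfer between the two dictionaries meaningful.
#'
#' @param mr MR `llm_volume` (typically intensity-normalized).
#' @param df the paired signed distance field (same shape).
#' @param roi a `roi_box` restricting the centers.
#' @param patch_edge odd patch edge length `s >= 3` (patch vectors have
#'   length `s^3`).
#' @param stride sampling stride in voxels (1 = densest).
#' @return An object of class `patch_pairs`: matrices `mr` and `df`
#'   (`n x s^3`), the `n x 3` matrix `centers`, and `patch_edge`.
#' @export
sample_patch_pairs <- function(mr, df, roi, patch_edge, stride = 1L) {
  mr <- as_volume(mr); df <- as_volume(df)
  stopifnot(inherits(roi, "roi_box"))
  if (!identical(dim(mr), dim(df))) stop("mr and df shapes differ", call. = FALSE)
  patch_edge <- as.integer(patch_edge)
  if (patch_edge < 3L || patch_edge %% 2L == 0L) {
    stop("patch_edge must be odd and >= 3", call. = FALSE)
  }
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (any(roi$upper > dim(mr))) stop("roi exceeds volume bounds", call. = FALSE)
  centers <- .patch_centers(dim(mr), roi, patch_edge, stride, inside_roi = FALSE)
  if (nrow(centers) == 0L) {
    stop("roi too small: no center admits a full ", patch_edge, "^3 patch", call. = FALSE)
  }
  structure(list(mr = .extract_patches(mr$data, centers, patch_edge),
                 df = .extract_patches(df$data, centers, patch_edge),
                 centers = centers, patch_edge = patch_edge),
            class = "patch_pairs")
}

#' @export
print.patch_pairs <- function(x, ...) {
  cat(sprintf("<patch_pairs> %d pairs, patch %d^3 (%d-vectors)\n",
              nrow(x$mr), x$patch_edge, ncol(x$mr)))
  invisible(x)
}

# row-bind patch_pairs from several subjects
.pool_pairs <- function(pair_list) {
  stopifnot(length(pair_list) >= 1L)
  edge <- pair_list[[1L]]$patch_edge
  structure(list(mr = do.call(rbind, lapply(pair_list, `[[`, "mr")),
                 df = do.call(rbind, lapply(pair_list, `[[`, "df")),
                 centers = do.call(rbind, lapply(pair_list, `[[`, "centers")),
                 patch_edge = edge),
            class = "patch_pairs")
}

#' Build a paired MR/DF dictionary by k-means
#'
#' The MR patch vectors are clustered by k-means (k-means++ seeding, Lloyd
#' updates, best of `n_restarts` restarts under `seed`); the cluster centers
#' become the MR atoms. Each DF atom is the plain arithmetic mean of the DF
#' patches of the pairs assigned to that cluster, so atom `i` of the two
#' dictionaries describes the same local neighborhood — the locally linear
#' map between MR and DF patch manifolds is what justifies reusing MR coding
#' weights on the DF atoms. A cluster emptied during Lloyd iteration is
#' re-seeded at the point farthest from its center, so exactly `n_atoms`
#' paired atoms always come back. When `n_atoms` equals the number of pairs
#' the pairs themselves are returned as atoms (the exact fixed point).
#'
#' @param pairs a `patch_pairs` object (see [sample_patch_pairs()]).
#' @param n_atoms number of dictionary atoms `M` (at most the number of pairs).
#' @param seed integer RNG seed; the build is reproducible given the seed.
#' @param n_restarts,max_iter,tol Lloyd controls: restarts kept best-of,
#'   iteration cap, and relative inertia-change stopping threshold.
#' @return An object of class `llm_dictionary` with `mr_atoms`, `df_atoms`
#'   (`M x s^3`), `patch_edge`, and a `meta` list (seed, training size,
#'   inertia, iterations, cluster sizes).
#' @export
build_dictionary <- function(pairs, n_atoms, seed = 0L, n_restarts = 3L,
                             max_iter = 300L, tol = 1e-4) {
  stopifnot(inherits(pairs, "patch_pairs"))
  n <- nrow(pairs$mr)
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("n_atoms must be >= 1", call. = FALSE)
  if (n_atoms > n) {
    stop("n_atoms (", n_atoms, ") exceeds the number of training pairs (", n, ")",
         call. = FALSE)
  }
  if (n_atoms == n) {
    fit <- list(centers = pairs$mr, assignment = seq_len(n), inertia = 0,
                iterations = 0L, n_restarts = 0L)
  } else {
    fit <- .patch_kmeans(pairs$mr, n_atoms, seed = seed, n_restarts = n_restarts,
                         max_iter = max_iter, tol = tol)
  }
  counts <- tabulate(fit$assignment, nbins = n_atoms)
  df_sums <- rowsum(pairs$df, fit$assignment, reorder = FALSE)
  df_atoms <- matrix(0, n_atoms, ncol(pairs$df))
  grp <- as.integer(rownames(df_sums))
  df_atoms[grp, ] <- df_sums / counts[grp]
  structure(list(mr_atoms = fit$centers, df_atoms = df_atoms,
                 patch_edge = pairs$patch_edge, assignment = fit$assignment,
                 meta = list(seed = as.integer(seed), n_training_pairs = n,
                             inertia = fit$inertia, iterations = fit$iterations,
                             n_restarts = fit$n_restarts, cluster_sizes = counts)),
            class = "llm_dictionary")
}

#' @export
print.llm_dictionary <- function(x, ...) {
  cat(sprintf("<llm_dictionary> %d paired atoms, patch %d^3, from %d pairs (inertia %.4g)\n",
              nrow(x$mr_atoms), x$patch_edge, x$meta$n_training_pairs, x$meta$inertia))
  invisible(x)
}

#' k nearest MR atoms of a patch vector
#'
#' Euclidean nearest neighbors among the dictionary's MR atoms, returned in
#' ascending order of distance with ties broken by lower atom index.
#'
#' @param dict an `llm_dictionary`.
#' @param x patch vector of the dictionary's vector length.
#' @param k number of neighbors, `1 <= k <= M`.
#' @return Integer vector of `k` atom indices.
#' @export
knn_query <- function(dict, x, k) {
  stopifnot(inherits(dict, "llm_dictionary"))
  x <- as.numeric(x)
  if (length(x) != ncol(dict$mr_atoms)) {
    stop("patch vector length ", length(x), " does not match dictionary atom length ",
         ncol(dict$mr_atoms), call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(dict$mr_atoms)) {
    stop("k must be between 1 and the number of atoms", call. = FALSE)
  }
  d2 <- rowSums(dict$mr_atoms^2) - 2 * as.numeric(dict$mr_atoms %*% x) + sum(x^2)
  order(d2, seq_along(d2))[seq_len(k)] # secondary key: lower index wins ties
}

#' Serialize / load a dictionary
#'
#' Dictionaries are stored with R's native serialization (version 3): the
#' paired atom matrices as 8-byte doubles plus the `patch_edge` and `meta`
#' provenance fields.
#'
#' @param dict an `llm_dictionary`.
#' @param path file path (conventionally `.rds`).
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns the `llm_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "llm_dictionary"))
  saveRDS(dict, path, version = 3L)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such dictionary file: ", path, call. = FALSE)
  dict <- readRDS(path)
  if (!inherits(dict, "llm_dictionary")) {
    stop(path, " does not contain an llm_dictionary", call. = FALSE)
  }
  dict
}
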