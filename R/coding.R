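#' Coding parameters
#'
#' Controls the local linear representation of a test MR patch over its `k`
#' nearest dictionary atoms.
#'
#' @param k neighbor count (default 30, the method's operating point).
#' @param method `"llc"` (locality-constrained linear coding; sum-to-one
#'   weights that may be negative) or `"lae"` (local anchor embedding;
#'   weights additionally constrained to the probability simplex).
#' @param ridge non-negative LLC regularizer, applied as
#'   `ridge * trace(Z Z') * I` on the local Gram matrix; guards duplicate or
#'   near-duplicate atoms.
#' @param lae_max_iter,lae_tol LAE projected-gradient solver controls
#'   (iteration cap; stopping threshold on the gradient-mapping norm).
#' @return An object of class `coding_params`.
#' @export
coding_params <- function(k = 30L, method = c("llc", "lae"), ridge = 1e-4,
                          lae_max_iter = 500L, lae_tol = 1e-8) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  structure(list(k = k, method = method, ridge = ridge,
                 lae_max_iter = as.integer(lae_max_iter), lae_tol = lae_tol),
            class = "coding_params")
}

# ---- solvers on a fixed neighbor matrix N (k x d, rows = atoms) ----

# LLC closed form: minimize |x - N'w|^2 (+ ridge) subject to sum(w) = 1.
# With Z = N - 1 x' the objective is w' Z Z' w, so w is proportional to
# C^{-1} 1 for C = Z Z' + ridge * tr(Z Z') * I, normalized to sum 1.
# Two exactly-solvable cases bypass the regularized system: (a) neighbors
# identical to x reconstruct it with residual 0, so the weight is spread
# uniformly over them (the unregularized optimum, deterministic tie-break);
# (b) with ridge = 0 a singular Gram matrix is handled by the bordered KKT
# system of the equality-constrained least-squares problem, which stays
# solvable whenever the minimizer is unique (e.g. x midway between two
# atoms).
.llc_weights <- function(x, N, ridge) {
  k <- nrow(N)
  if (k == 1L) return(1)
  Z <- sweep(N, 2L, x, "-")
  z_sq <- rowSums(Z^2)
  if (any(z_sq == 0)) {
    w <- numeric(k)
    w[z_sq == 0] <- 1 / sum(z_sq == 0)
    return(w)
  }
  C <- tcrossprod(Z)
  tr <- sum(z_sq)
  if (ridge > 0) {
    w <- solve(C + diag(ridge * tr, k), rep(1, k))
    return(as.numeric(w / sum(w)))
  }
  kkt <- rbind(cbind(2 * C, rep(1, k)), c(rep(1, k), 0))
  sol <- tryCatch(solve(kkt, c(numeric(k), 1)), error = function(e) {
    stop("singular LLC system with ridge = 0 (degenerate neighbor set); ",
         "use ridge > 0", call. = FALSE)
  })
  as.numeric(sol[seq_len(k)])
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(v)
  rho <- max(which(u - (css - 1) / j > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# LAE: minimize |x - N'w|^2 over the simplex by accelerated projected
# gradient (FISTA) with a gradient-mapping stopping rule; returns the best
# feasible iterate by objective.
.lae_weights <- function(x, N, max_iter, tol) {
  k <- nrow(N)
  if (k == 1L) return(1)
  z_sq <- rowSums(sweep(N, 2L, x, "-")^2)
  if (any(z_sq == 0)) { # exact matches: a vertex/face optimum with residual 0
    w <- numeric(k)
    w[z_sq == 0] <- 1 / sum(z_sq == 0)
    return(w)
  }
  G <- tcrossprod(N)
  b <- as.numeric(N %*% x)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(L) || L <= 0) return(rep(1 / k, k)) # all-zero atoms
  obj <- function(w) sum(w * (G %*% w)) - 2 * sum(b * w) + sum(x^2)
  w <- rep(1 / k, k)
  y <- w
  t_k <- 1
  best_w <- w
  best_obj <- obj(w)
  for (it in seq_len(max_iter)) {
    g <- 2 * (as.numeric(G %*% y) - b)
    w_new <- .project_simplex(y - g / L)
    o <- obj(w_new)
    if (o < best_obj) { best_obj <- o; best_w <- w_new }
    gm <- L * sqrt(sum((y - w_new)^2)) # gradient-mapping norm at y
    if (gm < tol) break
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    w <- w_new
    t_k <- t_new
  }
  best_w
}

.coding_result <- function(x, dict, idx, w, method) {
  recon <- as.numeric(crossprod(dict$mr_atoms[idx, , drop = FALSE], w))
  structure(list(neighbor_indices = idx, weights = as.numeric(w),
                 residual = sqrt(sum((x - recon)^2)), method = method),
            class = "coding_result")
}

#' @export
print.coding_result <- function(x, ...) {
  cat(sprintf("<coding_result> %s over %d atoms, residual %.4g\n",
              toupper(x$method), length(x$weights), x$residual))
  invisible(x)
}

#' Locality-constrained linear coding of a patch
#'
#' Represents `x` over its `k` nearest MR atoms with sum-to-one weights
#' minimizing the reconstruction error (hard-locality LLC, solved in closed
#' form on the local Gram matrix). Weights may be negative — that is the
#' defining contrast with [lae_code()]. The Euclidean reconstruction
#' residual is returned alongside and later drives the fusion confidence.
#'
#' @param x MR patch vector (length `s^3`).
#' @param dict an `llm_dictionary`.
#' @param params a `coding_params` with `method = "llc"`.
#' @return A `coding_result`: `neighbor_indices`, `weights` (sum 1), and
#'   `residual`.
#' @export
llc_code <- function(x, dict, params = coding_params()) {
  if (params$method != "llc") stop("params$method must be 'llc'", call. = FALSE)
  x <- as.numeric(x)
  idx <- knn_query(dict, x, params$k)
  w <- .llc_weights(x, dict$mr_atoms[idx, , drop = FALSE], params$ridge)
  .coding_result(x, dict, idx, w, "llc")
}

#' Local anchor embedding coding of a patch
#'
#' Like [llc_code()] but the weights are constrained to the probability
#' simplex (non-negative, sum one), so the patch is approximated by a convex
#' combination of its nearest atoms. Solved by accelerated projected
#' gradient with exact simplex projection. Its residual can never be smaller
#' than LLC's on the same neighbor set (the feasible set is a subset).
#'
#' @inheritParams llc_code
#' @param params a `coding_params` with `method = "lae"`.
#' @return A `coding_result` with non-negative weights.
#' @export
lae_code <- function(x, dict, params = coding_params(method = "lae")) {
  if (params$method != "lae") stop("params$method must be 'lae'", call. = FALSE)
  x <- as.numeric(x)
  idx <- knn_query(dict, x, params$k)
  w <- .lae_weights(x, dict$mr_atoms[idx, , drop = FALSE],
                    params$lae_max_iter, params$lae_tol)
  .coding_result(x, dict, idx, w, "lae")
}

#' Transfer coding weights to the DF dictionary
#'
#' The predicted DF patch is the weighted combination of the DF atoms paired
#' with the selected MR atoms, using the MR coding weights verbatim — the
#' locally linear MR-to-DF map is what licenses this transfer. Exactly
#' linear in the weights.
#'
#' @param code a `coding_result`.
#' @param dict the `llm_dictionary` the code was computed against.
#' @return Numeric DF patch vector of length `s^3`.
#' @export
predict_df_patch <- function(code, dict) {
  stopifnot(inherits(code, "coding_result"), inherits(dict, "llm_dictionary"))
  idx <- code$neighbor_indices
  if (any(idx < 1L) || any(idx > nrow(dict$df_atoms))) {
    stop("coding result does not match this dictionary (atom index out of range)",
         call. = FALSE)
  }
  as.numeric(crossprod(dict$df_atoms[idx, , drop = FALSE], code$weights))
}

# ---- batched coding used by segment_volume ----
# X: n x d matrix of test patches. Returns residuals (n), predictions
# (n x d), and the per-row codes' neighbor sets implicitly discarded.
.code_patch_matrix <- function(X, dict, params) {
  n <- nrow(X)
  d <- ncol(X)
  A <- dict$mr_atoms
  k <- params$k
  if (k > nrow(A)) stop("k exceeds the number of dictionary atoms", call. = FALSE)
  a_sq <- rowSums(A^2)
  x_sq <- rowSums(X^2)
  preds <- matrix(0, n, d)
  res <- numeric(n)
  chunk_rows <- max(1L, as.integer(2e6 / nrow(A)))
  start <- 1L
  tie_key <- seq_len(nrow(A))
  while (start <= n) {
    end <- min(n, start + chunk_rows - 1L)
    D <- sweep(-2 * tcrossprod(X[start:end, , drop = FALSE], A), 2L, a_sq, "+") +
      x_sq[start:end]
    for (i in start:end) {
      x <- X[i, ]
      idx <- order(D[i - start + 1L, ], tie_key)[seq_len(k)]
      Nmat <- A[idx, , drop = FALSE]
      w <- if (params$method == "llc") {
        .llc_weights(x, Nmat, params$ridge)
      } else {
        .lae_weights(x, Nmat, params$lae_max_iter, params$lae_tol)
      }
      res[i] <- sqrt(sum((x - as.numeric(crossprod(Nmat, w)))^2))
      preds[i, ] <- as.numeric(crossprod(dict$df_atoms[idx, , drop = FALSE], w))
    }
    start <- end + 1L
  }
  list(residual = res, pred = preds)
}
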