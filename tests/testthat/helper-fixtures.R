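# Shared fixtures: everything is generated in code at test time.

# small noiseless phantom with clean two-class structure
tiny_phantom <- function(grid = 24L, seed = 7L, blur = 0, noise = 0, texture = 0,
                         semi = c(3, min(6, grid / 4))) {
  generate_phantom(phantom_params(grid_size = grid, semi_axis_range = semi,
                                  blur_sigma = blur, noise_sd = noise,
                                  texture_sd = texture, seed = seed))
}

# random binary label volume guaranteed to contain both classes
random_label <- function(n = 12L, p = 0.2, seed = 1L) {
  set.seed(seed)
  repeat {
    lab <- array(as.numeric(runif(n^3) < p), dim = c(n, n, n))
    if (any(lab > 0) && !all(lab > 0)) return(volume(lab))
  }
}

# O(n^2) brute-force signed distance oracle: nearest opposite-class voxel
brute_force_sdf <- function(lab_vol) {
  lab <- lab_vol$data
  n <- dim(lab)
  co <- as.matrix(expand.grid(seq_len(n[1]), seq_len(n[2]), seq_len(n[3])))
  D2 <- as.matrix(dist(co))^2
  fg <- as.vector(lab > 0)
  out <- numeric(length(fg))
  for (i in seq_along(fg)) {
    opp <- if (fg[i]) !fg else fg
    out[i] <- (if (fg[i]) 1 else -1) * sqrt(min(D2[i, opp]))
  }
  array(out, dim = n)
}

# random patch_pairs object (centers are dummies; only vectors matter)
random_pairs <- function(n, d = 27L, seed = 1L, edge = 3L) {
  set.seed(seed)
  structure(list(mr = matrix(rnorm(n * d), n, d),
                 df = matrix(rnorm(n * d), n, d),
                 centers = matrix(1L, n, 3L), patch_edge = edge),
            class = "patch_pairs")
}

# dictionary straight from given atom matrices (bypasses clustering)
manual_dictionary <- function(mr_atoms, df_atoms = mr_atoms, patch_edge = 3L) {
  structure(list(mr_atoms = mr_atoms, df_atoms = df_atoms,
                 patch_edge = patch_edge, assignment = seq_len(nrow(mr_atoms)),
                 meta = list(seed = 0L, n_training_pairs = nrow(mr_atoms),
                             inertia = 0, iterations = 0L, n_restarts = 0L,
                             cluster_sizes = rep(1L, nrow(mr_atoms)))),
            class = "llm_dictionary")
}

# equality-constrained QP oracle for the LLC objective: minimize
# w' (Z Z' + ridge tr I) w subject to sum(w) = 1, solved through the full
# bordered KKT system (an independent route from the package's normalized
# C^{-1} 1 closed form).
llc_kkt_oracle <- function(x, N, ridge) {
  k <- nrow(N)
  Z <- sweep(N, 2L, x, "-")
  C <- tcrossprod(Z)
  if (ridge > 0) C <- C + diag(ridge * sum(diag(C)), k)
  sol <- solve(rbind(cbind(2 * C, rep(1, k)), c(rep(1, k), 0)),
               c(numeric(k), 1))
  sol[seq_len(k)]
}

# exhaustive simplex-grid search oracle for the LAE objective at k = 3
lae_grid_oracle <- function(x, N, step = 1e-3) {
  stopifnot(nrow(N) == 3L)
  G <- tcrossprod(N)
  b <- as.numeric(N %*% x)
  w1 <- seq(0, 1, by = step)
  best <- Inf
  for (a in w1) {
    w2 <- seq(0, 1 - a, by = step)
    w3 <- 1 - a - w2
    # objective = w'Gw - 2 b'w + |x|^2, vectorized over w2
    obj <- G[1, 1] * a^2 + G[2, 2] * w2^2 + G[3, 3] * w3^2 +
      2 * (G[1, 2] * a * w2 + G[1, 3] * a * w3 + G[2, 3] * w2 * w3) -
      2 * (b[1] * a + b[2] * w2 + b[3] * w3) + sum(x^2)
    best <- min(best, min(obj))
  }
  best
}

lae_objective <- function(x, N, w) sum((x - as.numeric(crossprod(N, w)))^2)
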