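# Synthetic phantom generator.
#
# Emulates the statistical structure the segmentation method faces on real
# hippocampus MRI at desk scale: a compact bright structure of 10-30 voxel
# extent (union of 1-3 bent ellipsoids) in a smoothly textured background,
# with partial-volume blur at the boundary and additive Gaussian noise,
# paired with the exact binary label. Phantoms share one coordinate frame,
# standing in for the linear-registration alignment of real cohorts.

# separable Gaussian blur, truncated at 4 sigma, replicate-padded edges
.gauss_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    n <- d[axis]
    idx <- function(i) pmin(pmax(i, 1L), n) # replicate padding
    out <- array(0, dim = d)
    for (j in seq_along(kern)) {
      sh <- j - r - 1L
      src <- switch(axis,
                    a[idx(seq_len(n) + sh), , , drop = FALSE],
                    a[, idx(seq_len(n) + sh), , drop = FALSE],
                    a[, , idx(seq_len(n) + sh), drop = FALSE])
      out <- out + kern[j] * src
    }
    out
  }
  arr <- conv_axis(arr, 1L)
  arr <- conv_axis(arr, 2L)
  conv_axis(arr, 3L)
}

#' Phantom parameters
#'
#' @param grid_size cubic grid edge in voxels (default 48).
#' @param n_ellipsoids number of ellipsoids forming the object (1-3).
#' @param semi_axis_range range the random semi-axes are drawn from, in
#'   voxels; the upper end may not exceed `grid_size / 4` so the object
#'   stays compact within the grid.
#' @param foreground_mean,background_mean object and background intensity
#'   (arbitrary units; only their contrast relative to the noise matters
#'   after normalization).
#' @param blur_sigma Gaussian blur of the label before intensity assignment,
#'   in voxels — this models the partial-volume weak boundary that makes
#'   the structure hard to delineate.
#' @param noise_sd additive white Gaussian noise sd.
#' @param texture_sd,texture_scale sd and correlation length (voxels) of the
#'   smooth background texture.
#' @param warp_amp maximum amplitude (voxels) of the smooth sinusoidal bend
#'   applied to each ellipsoid, giving the curved, hippocampus-like shape.
#' @param shift optional rigid integer voxel shift of the object (off by
#'   default: phantoms are generated aligned).
#' @param ellipsoids optional explicit list of ellipsoids (each a list with
#'   `center`, `semi_axes`, `bend_amp`, `bend_phase`); when `NULL` they are
#'   drawn at random from the ranges above.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_size = 48L, n_ellipsoids = 2L,
                           semi_axis_range = c(3, 10),
                           foreground_mean = 0.8, background_mean = 0.2,
                           blur_sigma = 1, noise_sd = 0.05,
                           texture_sd = 0.05, texture_scale = 8,
                           warp_amp = 2, shift = c(0L, 0L, 0L),
                           ellipsoids = NULL, seed = 0L) {
  grid_size <- as.integer(grid_size)
  n_ellipsoids <- as.integer(n_ellipsoids)
  if (grid_size < 8L) stop("grid_size must be >= 8", call. = FALSE)
  if (n_ellipsoids < 1L || n_ellipsoids > 3L) {
    stop("n_ellipsoids must be 1, 2 or 3", call. = FALSE)
  }
  if (length(semi_axis_range) != 2L || semi_axis_range[1L] < 1 ||
      diff(semi_axis_range) < 0) {
    stop("semi_axis_range must be an increasing positive pair", call. = FALSE)
  }
  if (semi_axis_range[2L] > grid_size / 4) {
    stop("grid_size must be at least 4x the largest semi-axis", call. = FALSE)
  }
  if (foreground_mean == background_mean) {
    stop("foreground_mean and background_mean must differ", call. = FALSE)
  }
  if (noise_sd < 0 || texture_sd < 0) stop("noise/texture sd must be >= 0", call. = FALSE)
  structure(list(grid_size = grid_size, n_ellipsoids = n_ellipsoids,
                 semi_axis_range = as.numeric(semi_axis_range),
                 foreground_mean = foreground_mean, background_mean = background_mean,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 texture_sd = texture_sd, texture_scale = texture_scale,
                 warp_amp = warp_amp, shift = as.integer(rep_len(shift, 3L)),
                 ellipsoids = ellipsoids, seed = as.integer(seed)),
            class = "phantom_params")
}

# draw a random ellipsoid set for the given params (RNG state is the caller's)
.draw_ellipsoids <- function(p) {
  g <- p$grid_size
  lapply(seq_len(p$n_ellipsoids), function(i) {
    list(center = g / 2 + runif(3, -g / 10, g / 10),
         semi_axes = sort(runif(3, p$semi_axis_range[1L], p$semi_axis_range[2L]),
                          decreasing = TRUE),
         bend_amp = runif(1, 0, p$warp_amp),
         bend_phase = runif(1, 0, 2 * pi))
  })
}

# rasterize the union of bent ellipsoids on the grid
.rasterize_label <- function(ellipsoids, g, shift) {
  co <- seq_len(g)
  X <- array(rep(co, times = g * g), dim = c(g, g, g))
  Y <- array(rep(rep(co, each = g), times = g), dim = c(g, g, g))
  Z <- array(rep(co, each = g * g), dim = c(g, g, g))
  lab <- array(FALSE, dim = c(g, g, g))
  for (e in ellipsoids) {
    ctr <- e$center + shift
    # smooth bend: the axis-1 coordinate is offset by a sinusoid in axis 3
    Xb <- X - e$bend_amp * sin(2 * pi * (Z - ctr[3L]) / g + e$bend_phase)
    q <- ((Xb - ctr[1L]) / e$semi_axes[1L])^2 +
      ((Y - ctr[2L]) / e$semi_axes[2L])^2 +
      ((Z - ctr[3L]) / e$semi_axes[3L])^2
    lab <- lab | (q <= 1)
  }
  lab
}

#' Generate one synthetic MR/label phantom pair
#'
#' The label is the voxelized union of the (optionally bent) ellipsoids; the
#' MR image is `background_mean + texture + contrast * blur(label) + noise`.
#' Deterministic given `params$seed`. If the drawn object is empty (warped
#' outside the grid) the centers are perturbed and the draw retried, up to
#' 10 attempts.
#'
#' @param params a `phantom_params`.
#' @return A list with elements `mr` (`llm_volume`), `label` (binary
#'   `llm_volume`), and `params` (with the realized ellipsoids filled in).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$grid_size
  with_seed(params$seed, {
    ell <- if (is.null(params$ellipsoids)) .draw_ellipsoids(params) else params$ellipsoids
    lab <- .rasterize_label(ell, g, params$shift)
    attempt <- 1L
    while ((!any(lab) || all(lab)) && attempt <= 10L) {
      ell <- lapply(ell, function(e) {
        e$center <- e$center + runif(3, -2, 2)
        e
      })
      lab <- .rasterize_label(ell, g, params$shift)
      attempt <- attempt + 1L
    }
    if (!any(lab) || all(lab)) {
      stop("degenerate phantom: object empty (or grid-filling) after 10 attempts",
           call. = FALSE)
    }
    mr <- params$background_mean +
      (params$foreground_mean - params$background_mean) *
        .gauss_blur3(array(as.numeric(lab), dim = dim(lab)), params$blur_sigma)
    if (params$texture_sd > 0) {
      tex <- .gauss_blur3(array(rnorm(g^3), dim = c(g, g, g)), params$texture_scale)
      mr <- mr + tex / sd(tex) * params$texture_sd
    }
    if (params$noise_sd > 0) {
      mr <- mr + array(rnorm(g^3, sd = params$noise_sd), dim = c(g, g, g))
    }
    params$ellipsoids <- ell
    list(mr = volume(mr, label = FALSE),
         label = volume(array(as.numeric(lab), dim = dim(lab)), label = TRUE),
         params = params)
  })
}

#' Generate a cohort of jittered phantoms
#'
#' All subjects share one base shape (drawn once from `seed` when `base`
#' does not fix the ellipsoids) and differ by per-subject jitter of the
#' ellipsoid centers and semi-axes and of the intensity means, emulating a
#' registered cohort: overlapping but distinct anatomies. Deterministic
#' given `seed`.
#'
#' @param n_subjects number of phantom pairs.
#' @param base a `phantom_params` for the shared shape and imaging model.
#' @param jitter list with `center` (max absolute voxel shift), `semi_axes`
#'   (max relative change), and `intensity` (max relative change of the two
#'   means).
#' @param seed cohort RNG seed.
#' @return List of `n_subjects` phantom pairs as from [generate_phantom()].
#' @export
generate_cohort <- function(n_subjects, base = phantom_params(),
                            jitter = list(center = 2, semi_axes = 0.15,
                                          intensity = 0.05),
                            seed = 0L) {
  stopifnot(inherits(base, "phantom_params"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  jit <- modifyList(list(center = 2, semi_axes = 0.15, intensity = 0.05), jitter)
  # the shared shape is a function of `base` alone (its own seed), so a
  # zero-jitter cohort of one reproduces generate_phantom(base) exactly
  base_ell <- if (is.null(base$ellipsoids)) {
    with_seed(base$seed, .draw_ellipsoids(base))
  } else {
    base$ellipsoids
  }
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      p <- base
      p$ellipsoids <- lapply(base_ell, function(e) {
        e$center <- e$center + runif(3, -jit$center, jit$center)
        e$semi_axes <- e$semi_axes * runif(3, 1 - jit$semi_axes, 1 + jit$semi_axes)
        e
      })
      p$foreground_mean <- base$foreground_mean *
        runif(1, 1 - jit$intensity, 1 + jit$intensity)
      p$background_mean <- base$background_mean *
        runif(1, 1 - jit$intensity, 1 + jit$intensity)
      p$seed <- sub_seeds[i]
      generate_phantom(p)
    })
  })
}
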