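#' Fusion parameters
#'
#' Controls how overlapping DF patch predictions are merged into one field.
#'
#' @param patch_edge odd patch edge; must match the dictionary used.
#' @param stride sliding step in voxels, `1 <= stride <= patch_edge`
#'   (a larger stride would leave voxels uncovered).
#' @param sigma_epsilon small positive constant added to the per-voxel
#'   minimum squared residual when adapting the confidence decay; defaults
#'   to `1e-6 * patch_edge^3`.
#' @param mode `"cwa"` (confidence-based weighted average) or `"average"`
#'   (all patch weights 1 — the ablation baseline).
#' @param sigma_sq optional fixed decay parameter overriding the local
#'   adaptation; mainly of diagnostic interest (a very large value makes
#'   CWA coincide with the plain average).
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(patch_edge = 7L, stride = 2L, sigma_epsilon = NULL,
                          mode = c("cwa", "average"), sigma_sq = NULL) {
  mode <- match.arg(mode)
  patch_edge <- as.integer(patch_edge)
  stride <- as.integer(stride)
  if (patch_edge < 3L || patch_edge %% 2L == 0L) {
    stop("patch_edge must be odd and >= 3", call. = FALSE)
  }
  if (stride < 1L || stride > patch_edge) {
    stop("stride must satisfy 1 <= stride <= patch_edge", call. = FALSE)
  }
  if (is.null(sigma_epsilon)) sigma_epsilon <- 1e-6 * patch_edge^3
  if (sigma_epsilon <= 0) stop("sigma_epsilon must be > 0", call. = FALSE)
  if (!is.null(sigma_sq) && sigma_sq <= 0) stop("sigma_sq must be > 0", call. = FALSE)
  structure(list(patch_edge = patch_edge, stride = stride,
                 sigma_epsilon = sigma_epsilon, mode = mode, sigma_sq = sigma_sq),
            class = "fusion_params")
}

#' Confidence weight of a patch prediction
#'
#' `exp(-residual_sq / sigma_sq)`: strictly decreasing in the squared coding
#' residual and in `(0, 1]`, so patches whose local linear representation
#' reconstructs the MR appearance well dominate the fused estimate.
#'
#' @param residual_sq squared coding residual(s), `>= 0`.
#' @param sigma_sq positive decay parameter.
#' @return Weight(s) in `(0, 1]`.
#' @export
cwa_weight <- function(residual_sq, sigma_sq) {
  if (any(sigma_sq <= 0)) stop("sigma_sq must be > 0", call. = FALSE)
  exp(-residual_sq / sigma_sq)
}

#' Locally adapted decay parameter
#'
#' The decay is tied to the most confident patch covering a voxel:
#' `sigma_sq = min(residual_sqs) + epsilon`. When one patch reconstructs
#' nearly perfectly the decay is tight and that patch dominates; when every
#' covering patch reconstructs poorly the decay relaxes and the fusion
#' approaches a plain average.
#'
#' @param residual_sqs non-empty collection of squared residuals.
#' @param epsilon positive stabilizer.
#' @return `min(residual_sqs) + epsilon`, always positive.
#' @export
adaptive_sigma_sq <- function(residual_sqs, epsilon) {
  if (length(residual_sqs) == 0L) {
    stop("no coverage: cannot adapt sigma from an empty residual set", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  min(residual_sqs) + epsilon
}

# DF value assigned to voxels the patch grid never reaches (outside the ROI):
# far background by fiat.
.DF_BACKGROUND <- -1e6

#' Segment a volume by local linear mapping
#'
#' Slides a patch grid over the ROI of a (normalized) test MR volume,
#' codes every patch over its nearest MR atoms, transfers the weights to
#' the paired DF atoms, and fuses the overlapping DF patch predictions into
#' one signed distance field, which is thresholded at zero into the final
#' label. Fusion is confidence-weighted: each patch carries one scalar
#' coding residual, every voxel it covers receives the weight
#' `exp(-r^2 / (min_r^2(p) + epsilon))` where `min_r^2(p)` is the smallest
#' squared residual among patches covering voxel `p` (two accumulation
#' passes: residual minima first, then the weighted sums). The patch grid
#' starts at the first valid center inside the ROI and appends one clamped
#' final center per axis, so every ROI voxel is covered whenever
#' `stride <= patch_edge`. Voxels outside the ROI are labeled background.
#' The procedure is fully deterministic.
#'
#' @param test_mr test MR `llm_volume`, already intensity-normalized on the
#'   same convention as the training images (see [normalize_intensity()]).
#' @param roi `roi_box` to segment within; must admit at least one patch.
#' @param dict an `llm_dictionary`.
#' @param coding a `coding_params`.
#' @param fusion a `fusion_params` whose `patch_edge` matches `dict`.
#' @return An object of class `llm_segmentation`: `df` (fused signed
#'   distance field), `label` (binary volume), `coverage` (per-voxel patch
#'   counts), `residuals` (per patch), `centers`, and `timings` (seconds per
#'   stage).
#' @export
segment_volume <- function(test_mr, roi, dict, coding = coding_params(),
                           fusion = fusion_params(dict$patch_edge)) {
  test_mr <- as_volume(test_mr)
  stopifnot(inherits(roi, "roi_box"), inherits(dict, "llm_dictionary"),
            inherits(coding, "coding_params"), inherits(fusion, "fusion_params"))
  if (fusion$patch_edge != dict$patch_edge) {
    stop("configuration error: fusion patch_edge (", fusion$patch_edge,
         ") differs from dictionary patch_edge (", dict$patch_edge, ")", call. = FALSE)
  }
  dims <- dim(test_mr)
  if (any(roi$upper > dims)) stop("roi exceeds volume bounds", call. = FALSE)

  t0 <- proc.time()[["elapsed"]]
  centers <- .patch_centers(dims, roi, fusion$patch_edge, fusion$stride,
                            inside_roi = TRUE)
  if (nrow(centers) == 0L) {
    stop("no coverage: roi does not admit a full ", fusion$patch_edge, "^3 patch",
         call. = FALSE)
  }
  X <- .extract_patches(test_mr$data, centers, fusion$patch_edge)
  t_extract <- proc.time()[["elapsed"]]

  coded <- .code_patch_matrix(X, dict, coding)
  r_sq <- coded$residual^2
  t_code <- proc.time()[["elapsed"]]

  off <- .patch_offsets(fusion$patch_edge, dims)
  base <- centers[, 1L] + (centers[, 2L] - 1L) * dims[1L] +
    (centers[, 3L] - 1L) * dims[1L] * dims[2L]
  n_vox <- prod(dims)
  weight_sum <- numeric(n_vox)
  weighted_sum <- numeric(n_vox)
  coverage <- integer(n_vox)

  if (fusion$mode == "cwa" && is.null(fusion$sigma_sq)) {
    # pass 1: per-voxel minimum squared residual over covering patches
    residual_min <- rep(Inf, n_vox)
    for (u in seq_len(nrow(centers))) {
      idx <- base[u] + off
      residual_min[idx] <- pmin(residual_min[idx], r_sq[u])
    }
    sigma_grid <- residual_min + fusion$sigma_epsilon
  }
  # pass 2: accumulate confidence-weighted predictions
  for (u in seq_len(nrow(centers))) {
    idx <- base[u] + off
    w <- if (fusion$mode == "average") {
      1
    } else if (is.null(fusion$sigma_sq)) {
      exp(-r_sq[u] / sigma_grid[idx])
    } else {
      exp(-r_sq[u] / fusion$sigma_sq)
    }
    weight_sum[idx] <- weight_sum[idx] + w
    weighted_sum[idx] <- weighted_sum[idx] + w * coded$pred[u, ]
    coverage[idx] <- coverage[idx] + 1L
  }
  df <- rep(.DF_BACKGROUND, n_vox)
  covered <- weight_sum > 0
  df[covered] <- weighted_sum[covered] / weight_sum[covered]
  t_fuse <- proc.time()[["elapsed"]]

  df_vol <- volume(array(df, dim = dims), spacing = test_mr$spacing,
                   affine = test_mr$affine, label = FALSE)
  structure(list(df = df_vol, label = df_to_label(df_vol),
                 coverage = array(coverage, dim = dims),
                 residuals = coded$residual, centers = centers,
                 coding = coding, fusion = fusion,
                 timings = c(extract = t_extract - t0, code = t_code - t_extract,
                             fuse = t_fuse - t_code)),
            class = "llm_segmentation")
}

#' @export
print.llm_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<llm_segmentation> %s voxels, %d patches (%s, %s), ",
                     "foreground %d voxels\n"),
              paste(dim(x$label$data), collapse = "x"), nrow(x$centers),
              toupper(x$coding$method), x$fusion$mode, sum(x$label$data)))
  cat(sprintf("  residuals: median %.4g [%.4g, %.4g]; %.2fs code, %.2fs fuse\n",
              stats::median(x$residuals), min(x$residuals), max(x$residuals),
              x$timings[["code"]], x$timings[["fuse"]]))
  invisible(x)
}

#' Mid-slice view of a segmentation
#'
#' Shows the axial mid-slice of the fused distance field with the predicted
#' label boundary overlaid.
#'
#' @param x an `llm_segmentation`.
#' @param slice slice index along the third axis (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.llm_segmentation <- function(x, slice = NULL, ...) {
  d <- dim(x$df$data)
  if (is.null(slice)) slice <- (d[3L] + 1L) %/% 2L
  sl <- x$df$data[, , slice]
  sl[sl <= .DF_BACKGROUND] <- NA
  graphics::image(seq_len(d[1L]), seq_len(d[2L]), sl,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "axis 1", ylab = "axis 2",
                  main = sprintf("fused DF, slice %d", slice), ...)
  if (any(x$label$data[, , slice] > 0)) {
    graphics::contour(seq_len(d[1L]), seq_len(d[2L]), x$label$data[, , slice],
                      levels = 0.5, add = TRUE, drawlabels = FALSE, lwd = 2)
  }
  invisible(x)
}
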