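#' Fit a local linear mapping segmentation model
#'
#' Trains the method on MR/label pairs that share one coordinate frame (real
#' data is expected linearly registered; phantoms are generated aligned).
#' For every subject the MR intensities are z-scored over the subject's ROI,
#' the label is converted to a signed Euclidean distance field, and aligned
#' MR/DF patch pairs are sampled on a stride grid inside the ROI. The pooled
#' pairs are compressed into a paired dictionary by k-means
#' ([build_dictionary()]). The returned model carries the dictionary, the
#' resolved configuration, and a default ROI (the union of the training
#' ROIs) used by [predict.llm()] on new volumes of the same frame.
#'
#' @param mr list of MR volumes (`llm_volume`, array, or NIfTI path).
#' @param label list of matching binary label volumes.
#' @param roi_mask optional list of binary ROI masks (e.g. a propagated
#'   template label); when omitted each subject's own label defines its ROI.
#' @param config an [llm_config()].
#' @return An object of class `llm`.
#' @examples
#' cohort <- generate_cohort(3, phantom_params(grid_size = 24L,
#'   semi_axis_range = c(3, 6)), seed = 1)
#' cfg <- llm_config(patch_edge = 5L, n_atoms = 64L, k = 8L,
#'   sample_stride = 3L)
#' fit <- llm_train(lapply(cohort, `[[`, "mr"),
#'                  lapply(cohort, `[[`, "label"), config = cfg)
#' print(fit)
#' @export
llm_train <- function(mr, label, roi_mask = NULL, config = llm_config()) {
  stopifnot(inherits(config, "llm_config"))
  load_vol <- function(x) if (is.character(x)) read_volume(x) else as_volume(x)
  mr <- lapply(mr, load_vol)
  label <- lapply(label, load_vol)
  if (length(mr) != length(label) || length(mr) == 0L) {
    stop("need equal-length, non-empty mr and label lists", call. = FALSE)
  }
  if (!is.null(roi_mask)) {
    roi_mask <- lapply(roi_mask, load_vol)
    if (length(roi_mask) != length(mr)) {
      stop("roi_mask list length differs from mr list", call. = FALSE)
    }
  }
  pair_list <- vector("list", length(mr))
  subject_pairs <- integer(length(mr))
  roi_lo <- NULL; roi_hi <- NULL
  for (i in seq_along(mr)) {
    if (!identical(dim(mr[[i]]), dim(label[[i]]))) {
      stop("subject ", i, ": mr and label shapes differ", call. = FALSE)
    }
    src <- if (is.null(roi_mask)) label[[i]] else roi_mask[[i]]
    roi <- tryCatch(roi_from_mask(src, margin = config$margin),
                    error = function(e) stop("subject ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    norm <- normalize_intensity(mr[[i]], mask_from_roi(roi, dim(mr[[i]]),
                                                       spacing = mr[[i]]$spacing,
                                                       affine = mr[[i]]$affine))
    df <- signed_distance_transform(label[[i]])
    pair_list[[i]] <- sample_patch_pairs(norm, df, roi, config$patch_edge,
                                         stride = config$sample_stride)
    subject_pairs[i] <- nrow(pair_list[[i]]$mr)
    roi_lo <- if (is.null(roi_lo)) roi$lower else pmin(roi_lo, roi$lower)
    roi_hi <- if (is.null(roi_hi)) roi$upper else pmax(roi_hi, roi$upper)
  }
  pooled <- .pool_pairs(pair_list)
  dict <- build_dictionary(pooled, n_atoms = config$n_atoms, seed = config$seed,
                           n_restarts = config$n_restarts)
  structure(list(dictionary = dict, config = config,
                 roi = roi_box(roi_lo, roi_hi), dims = dim(mr[[1L]]),
                 training = list(n_subjects = length(mr),
                                 pairs_per_subject = subject_pairs,
                                 n_pairs = nrow(pooled$mr))),
            class = "llm")
}

#' Segment a new volume with a fitted model
#'
#' Normalizes the test MR over the model's ROI (or a supplied mask), runs
#' the sliding-patch coding and confidence-weighted fusion, and thresholds
#' the fused distance field into a label. Purely deterministic.
#'
#' @param object a fitted `llm` model.
#' @param mr test MR volume (`llm_volume`, array, or NIfTI path), in the
#'   training frame.
#' @param roi_mask optional binary mask defining the ROI for this volume;
#'   defaults to the model's training ROI.
#' @param mode,stride,coder,k optional overrides of the fitted config.
#' @param ... unused.
#' @return An `llm_segmentation` (see [segment_volume()]).
#' @export
predict.llm <- function(object, mr, roi_mask = NULL, mode = NULL, stride = NULL,
                        coder = NULL, k = NULL, ...) {
  cfg <- object$config
  mr <- if (is.character(mr)) read_volume(mr) else as_volume(mr)
  roi <- if (is.null(roi_mask)) {
    if (!identical(dim(mr), object$dims)) {
      stop("volume shape ", paste(dim(mr), collapse = "x"),
           " differs from the training frame ", paste(object$dims, collapse = "x"),
           "; supply roi_mask", call. = FALSE)
    }
    object$roi
  } else {
    roi_from_mask(as_volume(roi_mask), margin = cfg$margin)
  }
  norm <- normalize_intensity(mr, mask_from_roi(roi, dim(mr), spacing = mr$spacing,
                                                affine = mr$affine))
  coding <- coding_params(k = if (is.null(k)) cfg$k else k,
                          method = if (is.null(coder)) cfg$coder else coder,
                          ridge = cfg$ridge, lae_max_iter = cfg$lae_max_iter,
                          lae_tol = cfg$lae_tol)
  fusion <- fusion_params(patch_edge = cfg$patch_edge,
                          stride = if (is.null(stride)) cfg$stride else stride,
                          sigma_epsilon = cfg$sigma_epsilon,
                          mode = if (is.null(mode)) cfg$mode else mode)
  segment_volume(norm, roi, object$dictionary, coding = coding, fusion = fusion)
}

#' @export
print.llm <- function(x, ...) {
  cat(sprintf("Local linear mapping segmentation model\n"))
  cat(sprintf("  dictionary: %d paired atoms, patch %d^3\n",
              nrow(x$dictionary$mr_atoms), x$dictionary$patch_edge))
  cat(sprintf("  trained on %d subject(s), %d patch pairs\n",
              x$training$n_subjects, x$training$n_pairs))
  cat(sprintf("  coding: %s, k=%d; fusion: %s, stride %d\n",
              toupper(x$config$coder), x$config$k, x$config$mode, x$config$stride))
  invisible(x)
}

#' @export
summary.llm <- function(object, ...) {
  sizes <- object$dictionary$meta$cluster_sizes
  out <- list(n_atoms = nrow(object$dictionary$mr_atoms),
              patch_edge = object$dictionary$patch_edge,
              n_training_pairs = object$training$n_pairs,
              n_subjects = object$training$n_subjects,
              inertia = object$dictionary$meta$inertia,
              kmeans_iterations = object$dictionary$meta$iterations,
              cluster_size_range = range(sizes),
              df_atom_range = range(object$dictionary$df_atoms),
              config = object$config)
  class(out) <- "summary.llm"
  out
}

#' @export
print.summary.llm <- function(x, ...) {
  cat(sprintf("llm model: %d atoms (patch %d^3) from %d pairs / %d subjects\n",
              x$n_atoms, x$patch_edge, x$n_training_pairs, x$n_subjects))
  cat(sprintf("  k-means inertia %.5g after %d iterations; cluster sizes %d..%d\n",
              x$inertia, x$kmeans_iterations,
              x$cluster_size_range[1L], x$cluster_size_range[2L]))
  cat(sprintf("  DF atom value range [%.3f, %.3f] voxels\n",
              x$df_atom_range[1L], x$df_atom_range[2L]))
  print(x$config)
  invisible(x)
}

#' Diagnostic plot of a fitted model
#'
#' Cluster occupancy (how evenly the training pairs spread over the atoms)
#' and the distribution of each DF atom's center value, whose sign says
#' whether the atom describes an inside- or outside-boundary neighborhood.
#'
#' @param x a fitted `llm` model.
#' @param ... unused.
#' @export
plot.llm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sizes <- sort(x$dictionary$meta$cluster_sizes, decreasing = TRUE)
  graphics::plot(sizes, type = "h", log = "y", xlab = "atom (sorted)",
                 ylab = "cluster size", main = "dictionary occupancy")
  ctr <- (x$dictionary$patch_edge^3 + 1L) %/% 2L
  graphics::hist(x$dictionary$df_atoms[, ctr], breaks = 30,
                 xlab = "DF atom center value (voxels)", main = "DF atoms")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Train from files and serialize the dictionary (command-layer helper)
#'
#' Reads NIfTI triples, fits [llm_train()], writes the model to `out` with
#' R serialization, and drops a JSON run manifest (resolved config, input
#' hashes, package version) alongside.
#'
#' @param train_mrs,train_labels character vectors of NIfTI paths.
#' @param roi_masks optional character vector of mask paths.
#' @param config an `llm_config`.
#' @param out output model path (`.rds`).
#' @return The fitted model, invisibly.
#' @export
train_command <- function(train_mrs, train_labels, roi_masks = NULL,
                          config = llm_config(), out) {
  if (length(train_mrs) != length(train_labels)) {
    stop("need as many label paths (", length(train_labels),
         ") as MR paths (", length(train_mrs), ")", call. = FALSE)
  }
  fit <- llm_train(as.list(train_mrs), as.list(train_labels),
                   roi_mask = if (is.null(roi_masks)) NULL else as.list(roi_masks),
                   config = config)
  saveRDS(fit, out, version = 3L)
  write_manifest(paste0(out, ".manifest.json"), config = config,
                 inputs = c(train_mrs, train_labels, roi_masks),
                 outputs = out,
                 extra = list(n_pairs = fit$training$n_pairs,
                              inertia = fit$dictionary$meta$inertia))
  invisible(fit)
}

#' Write a machine-readable run manifest
#'
#' @param path manifest path (JSON).
#' @param config the resolved `llm_config`.
#' @param inputs,outputs file paths; inputs are content-hashed (md5).
#' @param extra optional named list of run facts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), outputs = character(),
                           extra = list()) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  man <- list(package = "llmseg",
              version = as.character(utils::packageVersion("llmseg")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = unclass(config),
              inputs = if (length(inputs)) {
                data.frame(path = unlist(inputs),
                           md5 = unname(tools::md5sum(unlist(inputs))))
              } else NULL,
              outputs = outputs,
              extra = extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
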