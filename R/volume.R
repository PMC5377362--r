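#' Construct a volume
#'
#' A volume is a 3D scalar grid plus the voxel spacing (mm per voxel along
#' each axis) and a 4x4 voxel-to-world affine. The affine is carried through
#' unmodified by every operation in the package; nothing resamples or
#' reorients. A volume may play three roles: MR intensity image, binary label
#' image (values restricted to 0/1), or signed distance field.
#'
#' @param data 3D numeric array (each axis of length >= 1).
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(4)`.
#' @param label logical; mark this volume as a binary label image. If `NA`
#'   (default) the flag is set automatically when all values are 0 or 1.
#' @return An object of class `llm_volume`.
#' @seealso [read_volume()], [write_volume()]
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = diag(4), label = NA) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got ",
         if (is.array(data)) paste0(length(dim(data)), " dimensions") else class(data)[1L],
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive numbers", call. = FALSE)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix", call. = FALSE)
  storage.mode(data) <- "double"
  if (is.na(label)) label <- all(data %in% c(0, 1))
  if (isTRUE(label) && !all(data %in% c(0, 1))) {
    stop("a label volume may contain only the values 0 and 1", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, affine = affine, label = isTRUE(label)),
            class = "llm_volume")
}

#' Coerce to a volume
#'
#' @param x an `llm_volume`, a 3D array, or an `RNifti` image.
#' @param ... passed to [volume()] for array input.
#' @return An `llm_volume`.
#' @export
as_volume <- function(x, ...) {
  if (inherits(x, "llm_volume")) return(x)
  if (inherits(x, "niftiImage")) {
    return(volume(array(as.numeric(x), dim = dim(x)),
                  spacing = RNifti::pixdim(x),
                  affine = unclass(RNifti::xform(x))))
  }
  if (is.array(x)) return(volume(x, ...))
  stop("cannot coerce class ", class(x)[1L], " to a volume", call. = FALSE)
}

#' @export
dim.llm_volume <- function(x) dim(x$data)

#' @export
print.llm_volume <- function(x, ...) {
  cat(sprintf("<llm_volume> %s %s, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              if (x$label) "label" else "scalar",
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file (`.nii` or `.nii.gz`). Files stored with an
#' integer datatype whose values are all 0 or 1 are flagged as label volumes.
#'
#' @param path path to an existing NIfTI file.
#' @return An `llm_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D volume but ", path, " has ", length(d), " dimensions", call. = FALSE)
  }
  dat <- array(as.numeric(img), dim = d)
  hdr <- RNifti::niftiHeader(img)
  int_types <- c(2L, 4L, 8L, 256L, 512L, 768L) # NIfTI integer datatype codes
  is_label <- hdr$datatype %in% int_types && all(dat %in% c(0, 1))
  volume(dat, spacing = RNifti::pixdim(img),
         affine = unclass(RNifti::xform(img)), label = is_label)
}

#' Write a volume to NIfTI
#'
#' Labels are written as unsigned 8-bit integers, everything else as 32-bit
#' float. The affine is stored as both qform and sform.
#'
#' @param vol an `llm_volume` (or coercible).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (vol$label) "uint8" else "float")
  invisible(path)
}

#' Normalize MR intensity within a mask (z-score)
#'
#' Removes per-scan intensity scale and offset by mapping the image through
#' `(x - m) / s`, where `m` and `s` are the mean and standard deviation of
#' the intensities under the mask foreground. Voxels outside the mask are
#' transformed with the same affine map, so relative contrast is preserved
#' everywhere. This makes the Euclidean patch distances used by the coder
#' invariant to scanner gain and offset.
#'
#' @param mr MR `llm_volume` (or 3D array).
#' @param mask binary `llm_volume` of identical shape with at least two
#'   foreground voxels of non-constant intensity.
#' @return The normalized `llm_volume`.
#' @export
normalize_intensity <- function(mr, mask) {
  mr <- as_volume(mr)
  mask <- as_volume(mask)
  if (!identical(dim(mr), dim(mask))) {
    stop("mr and mask shapes differ: ", paste(dim(mr), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), call. = FALSE)
  }
  fg <- mask$data > 0
  if (sum(fg) < 2L) stop("mask must contain at least 2 foreground voxels", call. = FALSE)
  v <- mr$data[fg]
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: intensity is constant inside the mask", call. = FALSE)
  }
  out <- mr
  out$data <- (mr$data - mean(v)) / s
  out$label <- FALSE
  out
}

#' Rectangular region of interest (voxel box)
#'
#' Bounds are 1-based and inclusive on both ends, matching R array indexing:
#' the box contains voxels `lower[a]:upper[a]` along each axis `a`.
#'
#' @param lower,upper integer length-3 corner indices, `lower <= upper`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L) {
    stop("roi corners must have length 3", call. = FALSE)
  }
  if (any(lower < 1L) || any(lower > upper)) {
    stop("invalid roi box: need 1 <= lower <= upper on every axis", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%s] .. [%s] (%s voxels)\n",
              paste(x$lower, collapse = ","), paste(x$upper, collapse = ","),
              paste(x$upper - x$lower + 1L, collapse = "x")))
  invisible(x)
}

#' @export
dim.roi_box <- function(x) as.integer(x$upper - x$lower + 1L)

#' ROI around a mask
#'
#' The tight bounding box of the mask foreground, dilated by `margin` voxels
#' per axis and clipped to the volume bounds. With `margin = 0` the box is
#' minimal: every face touches at least one foreground voxel.
#'
#' @param mask binary `llm_volume` with at least one foreground voxel.
#' @param margin non-negative integer, scalar or length-3.
#' @return A `roi_box`.
#' @export
roi_from_mask <- function(mask, margin = 0L) {
  mask <- as_volume(mask)
  margin <- as.integer(rep_len(margin, 3L))
  if (any(margin < 0L)) stop("margin must be non-negative", call. = FALSE)
  idx <- which(mask$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: no foreground voxels", call. = FALSE)
  lo <- pmax(apply(idx, 2L, min) - margin, 1L)
  hi <- pmin(apply(idx, 2L, max) + margin, dim(mask$data))
  roi_box(lo, hi)
}

#' Binary mask filled over an ROI box
#'
#' @param roi a `roi_box`.
#' @param dim_out integer length-3 volume shape.
#' @param spacing,affine passed to [volume()].
#' @return A label `llm_volume` that is 1 inside `roi` and 0 elsewhere.
#' @export
mask_from_roi <- function(roi, dim_out, spacing = c(1, 1, 1), affine = diag(4)) {
  stopifnot(inherits(roi, "roi_box"))
  dim_out <- as.integer(dim_out)
  if (any(roi$upper > dim_out)) stop("roi exceeds volume bounds", call. = FALSE)
  m <- array(0, dim = dim_out)
  m[roi$lower[1L]:roi$upper[1L],
    roi$lower[2L]:roi$upper[2L],
    roi$lower[3L]:roi$upper[3L]] <- 1
  volume(m, spacing = spacing, affine = affine, label = TRUE)
}
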