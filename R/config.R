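#' Run configuration
#'
#' All tunables of the pipeline in one validated object. The defaults record
#' the method's full-scale operating point (patch edge 7, 70,000-atom
#' dictionary, 30 neighbors, LLC coding, CWA fusion); controlled experiments
#' override `n_atoms` and the strides to the scale of their data.
#'
#' @param patch_edge odd patch edge length (default 7).
#' @param stride fusion sliding step in voxels (default 2).
#' @param n_atoms dictionary size (default 70000).
#' @param k neighbor count for coding (default 30).
#' @param coder `"llc"` or `"lae"`.
#' @param ridge LLC Gram regularizer (default 1e-4).
#' @param sigma_epsilon CWA stabilizer; `NULL` means `1e-6 * patch_edge^3`.
#' @param seed RNG seed for dictionary construction (default 0).
#' @param mode fusion mode, `"cwa"` or `"average"`.
#' @param sample_stride training patch sampling stride (default 1, densest).
#' @param margin ROI margin in voxels; `NULL` means `patch_edge %/% 2 + 2`,
#'   so every patch center needed for fusion fits inside the box.
#' @param n_restarts k-means restarts (default 3).
#' @param lae_max_iter,lae_tol LAE solver controls.
#' @return An object of class `llm_config` (a validated named list).
#' @export
llm_config <- function(patch_edge = 7L, stride = 2L, n_atoms = 70000L, k = 30L,
                       coder = c("llc", "lae"), ridge = 1e-4,
                       sigma_epsilon = NULL, seed = 0L,
                       mode = c("cwa", "average"), sample_stride = 1L,
                       margin = NULL, n_restarts = 3L,
                       lae_max_iter = 500L, lae_tol = 1e-8) {
  coder <- match.arg(coder)
  mode <- match.arg(mode)
  patch_edge <- as.integer(patch_edge)
  if (is.na(patch_edge) || patch_edge < 3L || patch_edge %% 2L == 0L) {
    stop("patch_edge must be an odd integer >= 3", call. = FALSE)
  }
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L || stride > patch_edge) {
    stop("stride must satisfy 1 <= stride <= patch_edge", call. = FALSE)
  }
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1L) stop("n_atoms must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  if (is.null(margin)) margin <- patch_edge %/% 2L + 2L
  margin <- as.integer(margin)
  if (any(is.na(margin)) || any(margin < 0L)) stop("margin must be >= 0", call. = FALSE)
  sample_stride <- as.integer(sample_stride)
  if (is.na(sample_stride) || sample_stride < 1L) {
    stop("sample_stride must be >= 1", call. = FALSE)
  }
  if (is.null(sigma_epsilon)) sigma_epsilon <- 1e-6 * patch_edge^3
  if (sigma_epsilon <= 0) stop("sigma_epsilon must be > 0", call. = FALSE)
  structure(list(patch_edge = patch_edge, stride = stride, n_atoms = n_atoms,
                 k = k, coder = coder, ridge = ridge,
                 sigma_epsilon = sigma_epsilon, seed = as.integer(seed),
                 mode = mode, sample_stride = sample_stride, margin = margin,
                 n_restarts = as.integer(n_restarts),
                 lae_max_iter = as.integer(lae_max_iter), lae_tol = lae_tol),
            class = "llm_config")
}

#' @export
print.llm_config <- function(x, ...) {
  cat(sprintf(paste0("<llm_config> patch %d^3, %d atoms, k=%d, %s/%s, stride %d ",
                     "(sample %d), ridge %g, seed %d\n"),
              x$patch_edge, x$n_atoms, x$k, toupper(x$coder), x$mode, x$stride,
              x$sample_stride, x$ridge, x$seed))
  invisible(x)
}

# keys a config file / CLI may set, with coercion functions
.config_fields <- function() {
  list(patch_edge = as.integer, stride = as.integer, n_atoms = as.integer,
       k = as.integer, coder = as.character, ridge = as.numeric,
       sigma_epsilon = as.numeric, seed = as.integer, mode = as.character,
       sample_stride = as.integer, margin = as.integer,
       n_restarts = as.integer, lae_max_iter = as.integer,
       lae_tol = as.numeric)
}

#' Load a configuration file
#'
#' Reads a flat configuration — either JSON or `key = value` lines (`#`
#' comments allowed) — validates it against the documented fields, and
#' resolves precedence as defaults < file < `overrides` (e.g. CLI flags).
#' Unknown keys are rejected.
#'
#' @param path config file path, or `NULL` for defaults-plus-overrides.
#' @param overrides named list overriding file values.
#' @return A validated `llm_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    txt <- readLines(path, warn = FALSE)
    first <- regmatches(paste(txt, collapse = "\n"),
                        regexpr("[^[:space:]]", paste(txt, collapse = "\n")))
    if (length(first) == 1L && first == "{") {
      vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
    } else {
      txt <- sub("#.*$", "", txt)
      txt <- trimws(txt)
      txt <- txt[nzchar(txt)]
      kv <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_]*)[[:space:]]*=[[:space:]]*(.*)$", txt))
      bad <- txt[vapply(kv, length, 1L) != 3L]
      if (length(bad) > 0L) {
        stop("cannot parse config line: '", bad[1L], "'", call. = FALSE)
      }
      vals <- stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                              vapply(kv, `[[`, "", 2L))
    }
  }
  fields <- .config_fields()
  apply_set <- function(acc, set, what) {
    if (length(set) == 0L) return(acc)
    unknown <- setdiff(names(set), names(fields))
    if (length(unknown) > 0L) {
      stop("unknown config key", if (length(unknown) > 1L) "s" else "", " in ",
           what, ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(set)) acc[[nm]] <- fields[[nm]](set[[nm]])
    acc
  }
  vals <- apply_set(list(), vals, "file")
  vals <- apply_set(vals, overrides, "overrides")
  do.call(llm_config, vals)
}
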