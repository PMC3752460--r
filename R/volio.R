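#' @useDynLib rsndr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd fft pnorm dnorm dgamma median quantile qbeta var
#' @importFrom utils combn read.delim write.csv modifyList
NULL

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from a parent seed; keeps values < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 30269) %% 2147483562) + 1L
}

#' Construct a 4D BOLD volume
#'
#' The common in-memory representation every pipeline stage shares: a numeric
#' X x Y x Z x T array with a voxel-to-mm affine and the repetition time.
#' 3D arrays are promoted to a single time point. All stages require inputs on
#' an identical grid (same dimensions and affine) and refuse to resample.
#'
#' @param data numeric array, 3D or 4D (X x Y x Z x T), all values finite.
#' @param affine 4x4 voxel-index-to-mm transform (RAS+).
#' @param tr repetition time in seconds (> 0).
#' @return An object of class `volume4d` with fields `data`, `affine`, `tr`.
#' @export
volume4d <- function(data, affine = diag(c(4, 4, 4, 1)), tr = 1.8) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3D or 4D array")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) stop(sprintf("data contains %d non-finite voxel values", nbad))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("tr must be a positive scalar (seconds)")
  }
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d timepoint(s), TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Construct a brain mask
#'
#' @param data logical (or 0/1 numeric) 3D array; at least one voxel must be
#'   TRUE.
#' @param affine 4x4 voxel-to-mm transform shared with companion volumes.
#' @return An object of class `brain_mask` with logical `data` and `affine`.
#' @export
brain_mask <- function(data, affine = diag(c(4, 4, 4, 1))) {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) stop("mask contains NA")
  if (!any(data)) stop("mask has no TRUE voxels")
  structure(list(data = data, affine = as.matrix(affine)), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d voxels in mask\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

grid_dim <- function(x) {
  if (inherits(x, "volume4d")) dim(x$data)[1:3] else dim(x$data)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch between %s: shapes %s vs %s (resampling is not supported)",
                 what, paste(grid_dim(a), collapse = "x"),
                 paste(grid_dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii` / `.nii.gz` file into a [volume4d()]. 3D files load with a
#' single time point. The repetition time is taken from `pixdim[4]` when the
#' file is 4D; a non-positive stored TR falls back to `default_tr`.
#'
#' @param path path to a NIfTI-1 file.
#' @param default_tr TR (seconds) used when the header does not carry one.
#' @return A [volume4d()].
#' @export
read_volume4d <- function(path, default_tr = 1.8) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) stop(sprintf("%s contains %d non-finite voxel values", path, nbad))
  pd <- RNifti::pixdim(img)
  tr <- if (length(dim(data)) >= 4L && length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0) {
    pd[4]
  } else {
    default_tr
  }
  volume4d(data, affine = unclass(RNifti::xform(img))[1:4, 1:4], tr = tr)
}

#' Read a NIfTI-1 mask
#'
#' @param path path to a NIfTI-1 file storing 0/1 values.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume4d(path)
  brain_mask(v$data[, , , 1] != 0, affine = v$affine)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float64 so that a read-back reproduces the data
#' bit-wise; masks are stored as 8-bit integers with 0/1 values.
#'
#' @param path output path (`.nii` or `.nii.gz`).
#' @param vol a [volume4d()] or [brain_mask()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, vol) {
  if (inherits(vol, "brain_mask")) {
    data <- array(as.integer(vol$data), dim = dim(vol$data))
    dtype <- "uint8"
    affine <- vol$affine
    tr <- NULL
  } else if (inherits(vol, "volume4d")) {
    data <- vol$data
    if (dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
    dtype <- "double"
    affine <- vol$affine
    tr <- vol$tr
  } else {
    stop("vol must be a volume4d or brain_mask")
  }
  img <- RNifti::asNifti(data)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- if (is.null(tr) || length(dim(data)) == 3L) vox else c(vox, tr)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a design table
#'
#' Tab-separated text with a header row and columns `subject_id`, `group`
#' (`patient` / `control`), `bold_path`, and optionally `gm_path`.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` validated by [design_table()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df <- design_table(df)
  # resolve paths stored relative to the design file
  for (col in c("bold_path", "gm_path")) {
    p <- as.character(df[[col]])
    ok <- which(!is.na(p))
    rel <- ok[!file.exists(p[ok])]
    p[rel] <- file.path(dirname(path), p[rel])
    df[[col]] <- p
  }
  df
}

#' Validate a design table
#'
#' @param df data.frame with columns `subject_id`, `group`, `bold_path` and
#'   optionally `gm_path`.
#' @return The validated data.frame with class `design_table` prepended.
#' @export
design_table <- function(df) {
  need <- c("subject_id", "group", "bold_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("subject_id values must be unique")
  if (!all(df$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  if (!all(c("patient", "control") %in% df$group)) {
    stop("both groups must be non-empty")
  }
  if (!"gm_path" %in% names(df)) df$gm_path <- NA_character_
  class(df) <- unique(c("design_table", class(df)))
  df
}

#' Write a design table as TSV
#'
#' @param design a [design_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract masked time-by-voxel matrices from volumes
#'
#' Column `v` of every returned matrix corresponds to the same voxel; the
#' voxel index map (linear indices into the 3D grid, column-major) inverts the
#' masking exactly via [unmask()].
#'
#' @param vols a [volume4d()] or list of them, all on the mask's grid.
#' @param mask a [brain_mask()].
#' @return List with `mats` (list of T x V matrices), `voxels` (integer index
#'   map), `dim` (grid shape) and `affine`.
#' @export
mask_to_matrix <- function(vols, mask) {
  if (inherits(vols, "volume4d")) vols <- list(vols)
  idx <- which(mask$data)
  nxyz <- prod(dim(mask$data))
  mats <- lapply(vols, function(v) {
    stop_if_grid_mismatch(v, mask, "volume and mask")
    d <- dim(v$data)
    m <- matrix(v$data, nrow = nxyz, ncol = d[4])
    t(m[idx, , drop = FALSE])
  })
  list(mats = mats, voxels = idx, dim = dim(mask$data), affine = mask$affine)
}

#' Restore masked values to the 3D (or 4D) grid
#'
#' @param x numeric vector of length V, or a matrix with V columns (each row
#'   becomes one 3D volume along the 4th axis).
#' @param mask a [brain_mask()].
#' @param fill value outside the mask (default 0).
#' @return A 3D array (vector input) or 4D array (matrix input).
#' @export
unmask <- function(x, mask, fill = 0) {
  idx <- which(mask$data)
  d <- dim(mask$data)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(idx))
    out <- array(fill, dim = c(d, nrow(x)))
    step <- prod(d)
    for (r in seq_len(nrow(x))) out[idx + (r - 1L) * step] <- x[r, ]
    out
  } else {
    stopifnot(length(x) == length(idx))
    out <- array(fill, dim = d)
    out[idx] <- x
    out
  }
}

#' Ellipsoid analysis mask
#'
#' Convenience constructor for the synthetic cohorts: an axis-aligned
#' ellipsoid centred in the grid.
#'
#' @param grid integer vector of 3 grid dimensions.
#' @param semiaxes ellipsoid semi-axes in voxels (length 3); default scales
#'   with the grid to give a compact central "brain".
#' @param center ellipsoid centre in voxel coordinates (default grid centre).
#' @param affine affine for the mask.
#' @return A [brain_mask()].
#' @export
ellipsoid_mask <- function(grid, semiaxes = grid * c(0.23, 0.23, 0.25),
                           center = (grid + 1) / 2,
                           affine = diag(c(4, 4, 4, 1))) {
  ii <- slice.index(array(0, grid), 1)
  jj <- slice.index(array(0, grid), 2)
  kk <- slice.index(array(0, grid), 3)
  r2 <- ((ii - center[1]) / semiaxes[1])^2 +
    ((jj - center[2]) / semiaxes[2])^2 +
    ((kk - center[3]) / semiaxes[3])^2
  brain_mask(r2 <= 1, affine = affine)
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable spatial convolution applied to each time point. The kernel width
#' is given as sigma in mm (FWHM = 2.355 sigma) and converted to voxels via
#' the affine; the gray-matter covariate maps are smoothed with sigma 3 mm by
#' default, mirroring common VBM practice.
#'
#' @param vol a [volume4d()].
#' @param sigma_mm Gaussian sigma in mm.
#' @return A smoothed [volume4d()].
#' @export
smooth_volume <- function(vol, sigma_mm = 3) {
  stopifnot(inherits(vol, "volume4d"))
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  out <- vol$data
  for (ax in 1:3) {
    sig <- sigma_mm / vox[ax]
    if (sig <= 1e-8) next
    half <- max(1L, ceiling(3 * sig))
    k <- dnorm(seq(-half, half), sd = sig)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  volume4d(out, affine = vol$affine, tr = vol$tr)
}

# 1D convolution along one spatial axis with edge replication of zeros
# (kernel renormalized at the borders so constants are preserved).
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  half <- (length(k) - 1L) / 2L
  n <- d[axis]
  out <- array(0, dim = d)
  wsum <- array(0, dim = d)
  for (o in seq(-half, half)) {
    w <- k[o + half + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    idx_dst <- which(ok)
    idx_src <- src[ok]
    dst_sel <- src_sel <- rep(list(quote(expr = )), length(d))
    dst_sel[[axis]] <- idx_dst
    src_sel[[axis]] <- idx_src
    out_slice <- do.call(`[`, c(list(arr), src_sel, list(drop = FALSE)))
    out <- out + w * do.call(`[<-`, c(list(array(0, d)), dst_sel, list(value = out_slice)))
    ones <- array(0, d)
    ones <- do.call(`[<-`, c(list(ones), dst_sel, list(value = w)))
    wsum <- wsum + ones
  }
  out / wsum
}
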