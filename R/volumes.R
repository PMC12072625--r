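# Low-level 3D array helpers shared by the phantom generator and the
# segmentation stage. Volumes are plain 3D numeric/logical arrays; voxel
# spacing (mm, length 3) is carried alongside, not inside, the array.

# Shift an array by (dx, dy, dz) voxels, zero-filling the vacated border.
.shift3 <- function(arr, d) {
  dm <- dim(arr)
  out <- array(0, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      if (d[a] >= dm[a]) return(out)
      src[[a]] <- seq_len(dm[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      if (-d[a] >= dm[a]) return(out)
      dst[[a]] <- seq_len(dm[a] + d[a])
      src[[a]] <- dst[[a]] - d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# Offsets of the 26-neighborhood (3x3x3 minus center) or the in-plane
# 8-neighborhood (3x3 minus center, same slice).
.neighbor_offsets <- function(kernel = c("3d26", "inplane8")) {
  kernel <- match.arg(kernel)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = if (kernel == "3d26") -1:1 else 0)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# Separable Gaussian smoothing with zero padding (exactly what normalized
# convolution needs). sigma_vox is per-axis, in voxels; an axis with sigma
# below ~1e-3 voxels is left untouched.
.gaussian_smooth3 <- function(arr, sigma_vox) {
  out <- arr
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 1e-3) next
    m <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-m:m, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim(out))
    for (j in seq_along(w)) {
      d <- c(0L, 0L, 0L)
      d[a] <- (-m:m)[j]
      acc <- acc + w[j] * .shift3(out, d)
    }
    out <- acc
  }
  out
}

# Physical coordinates (mm) of voxel centers along each axis: (i - 0.5) * sp.
.axis_mm <- function(n, sp) (seq_len(n) - 0.5) * sp

.check_same_shape <- function(...) {
  arrs <- list(...)
  dims <- lapply(arrs, dim)
  ok <- vapply(dims, function(d) identical(d, dims[[1]]), logical(1))
  if (!all(ok)) {
    stop("volumes do not share a common shape: ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = " vs "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' keep the package's plain-array convention: `read_volume()` returns a list
#' with `values` (a 3D array, with NIfTI attributes stripped) and `spacing`
#' (voxel size in mm); `write_volume()` stamps `spacing` into the NIfTI
#' header. Voxel coordinates throughout the package are 1-based array
#' indices; world coordinates live in the NIfTI affine.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param values A 3D array.
#' @param spacing Voxel size in mm, length 3.
#' @param datatype NIfTI storage type, e.g. `"float"` or `"int32"`.
#' @return `read_volume()`: list with `values` and `spacing`;
#'   `write_volume()`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  list(values = vals, spacing = as.numeric(sp))
}

#' @rdname read_volume
#' @export
write_volume <- function(values, spacing, path, datatype = "float") {
  img <- RNifti::asNifti(array(as.numeric(values), dim = dim(values)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
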