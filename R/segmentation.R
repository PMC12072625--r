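# PVS segmentation by local intensity contrast.
#
# A voxel inside the white-matter/basal-ganglia masks is called PVS when its
# intensity exceeds the mean of its surrounding voxels by more than a
# threshold (default 60, strictly greater). Supra-threshold voxels touching
# by face, edge or corner (26-connectivity) form one cluster.

#' Segmentation configuration
#'
#' @param diff_threshold Local intensity-difference threshold; a voxel is PVS
#'   only if its contrast is strictly greater than this value. The default 60
#'   presupposes intensities on a uniformized T2 scale with parenchyma around
#'   100; it is fully configurable because the absolute value is tied to the
#'   acquisition convention.
#' @param kernel Local-contrast neighborhood: `"3d26"` (3x3x3 minus center,
#'   26 surrounding voxels, the default) or `"inplane8"` (3x3 minus center in
#'   the axial plane, acknowledging slices much thicker than a PVS).
#' @param connectivity Cluster connectivity; fixed at 26 (edges-or-corners
#'   contact).
#' @param uniformize Apply bias-field uniformization before computing
#'   contrasts.
#' @param fwhm_mm Full width at half maximum, in mm, of the Gaussian used to
#'   estimate the low-frequency intensity field during uniformization.
#' @return A list of class `pvs_segmentation_config`.
#' @export
segmentation_config <- function(diff_threshold = 60,
                                kernel = c("3d26", "inplane8"),
                                connectivity = 26,
                                uniformize = TRUE,
                                fwhm_mm = 12) {
  kernel <- match.arg(kernel)
  if (!is.numeric(diff_threshold) || length(diff_threshold) != 1 ||
      diff_threshold <= 0) {
    stop("`diff_threshold` must be a single positive number", call. = FALSE)
  }
  if (!identical(as.integer(connectivity), 26L)) {
    stop("`connectivity` is fixed at 26 (edges-or-corners contact)",
         call. = FALSE)
  }
  structure(
    list(diff_threshold = diff_threshold, kernel = kernel,
         connectivity = 26L, uniformize = isTRUE(uniformize),
         fwhm_mm = fwhm_mm),
    class = "pvs_segmentation_config"
  )
}

#' Uniformize image intensity within a mask
#'
#' Estimates the low-frequency intensity field by normalized convolution
#' (Gaussian smoothing of the masked image divided by the smoothed mask),
#' divides it out, and rescales so the median intensity inside the mask is
#' preserved. Two estimation passes are run by default, which removes most of
#' the residual field that a single masked smoothing pass leaves near the
#' mask boundary. On an already-flat image the operation is the identity up
#' to numerical tolerance. Voxels outside the mask are returned unchanged.
#'
#' @param volume 3D numeric array.
#' @param mask Logical/0-1 array of the same shape; must contain at least one
#'   voxel.
#' @param spacing Voxel size in mm, length 3.
#' @param fwhm_mm Gaussian FWHM in mm for the field estimate.
#' @param iterations Number of estimate-and-divide passes.
#' @return The uniformized array.
#' @export
uniformize <- function(volume, mask, spacing, fwhm_mm = 12, iterations = 2) {
  .check_same_shape(volume, mask)
  m <- array(as.numeric(mask != 0), dim(mask))
  if (sum(m) == 0) stop("uniformize: mask is empty", call. = FALSE)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing
  sm <- .gaussian_smooth3(m, sigma_vox)
  out <- volume
  for (k in seq_len(iterations)) {
    num <- .gaussian_smooth3(out * m, sigma_vox)
    field <- ifelse(sm > 1e-8, num / pmax(sm, 1e-8), 1)
    field[field <= 0] <- 1
    out <- ifelse(m > 0, out / field, out)
  }
  med_in <- stats::median(volume[m > 0])
  med_out <- stats::median(out[m > 0])
  if (med_out != 0) out[m > 0] <- out[m > 0] * (med_in / med_out)
  out
}

#' Voxel-wise local intensity contrast
#'
#' For every voxel inside the mask, returns the voxel intensity minus the
#' mean of its surrounding voxels (the center is never part of its own
#' neighborhood). At the volume border the neighborhood is truncated to
#' in-volume coordinates, so the mean is over however many neighbors exist.
#' Voxels outside the mask get 0.
#'
#' @inheritParams uniformize
#' @param kernel `"3d26"` or `"inplane8"`; see [segmentation_config()].
#' @return Numeric array of contrasts.
#' @export
local_contrast <- function(volume, mask, kernel = c("3d26", "inplane8")) {
  kernel <- match.arg(kernel)
  .check_same_shape(volume, mask)
  offs <- .neighbor_offsets(kernel)
  nsum <- array(0, dim(volume))
  ncnt <- array(0, dim(volume))
  ones <- array(1, dim(volume))
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    nsum <- nsum + .shift3(volume, d)
    ncnt <- ncnt + .shift3(ones, d)
  }
  contrast <- (volume - nsum / pmax(ncnt, 1)) * (mask != 0)
  contrast
}

#' Segment PVS voxels
#'
#' Applies (optionally) uniformization over the union of the white-matter and
#' basal-ganglia masks, computes the local contrast, and marks as PVS every
#' masked voxel whose contrast strictly exceeds `config$diff_threshold` (a
#' contrast of exactly the threshold is not a PVS).
#'
#' @param volume 3D intensity array (T2-like, co-registered).
#' @param wm_mask,bg_mask Logical/0-1 arrays, same shape as `volume`.
#' @param spacing Voxel size in mm, length 3.
#' @param config A [segmentation_config()].
#' @return Logical array: the PVS mask.
#' @export
segment_pvs <- function(volume, wm_mask, bg_mask, spacing,
                        config = segmentation_config()) {
  .check_same_shape(volume, wm_mask, bg_mask)
  mask <- (wm_mask != 0) | (bg_mask != 0)
  vol <- volume
  if (config$uniformize) {
    vol <- uniformize(vol, mask, spacing, fwhm_mm = config$fwhm_mm)
  }
  contrast <- local_contrast(vol, mask, kernel = config$kernel)
  (contrast > config$diff_threshold) & mask
}

# 26-connectivity connected-component labeling over the sparse voxel set,
# union-find with path halving. Returns NULL for an empty mask, else a list
# with the voxel coordinate matrix and a component id per voxel.
.label_components <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask != 0)
  n <- length(idx)
  if (n == 0) return(NULL)
  pos <- array(0L, dm)
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dm)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- .neighbor_offsets("3d26")
  # half of the 26 offsets suffices: each pair is visited once
  half <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  for (r in seq_len(nrow(half))) {
    nb <- sweep(coords, 2, half[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    i_ok <- which(ok)
    nidx <- (nb[i_ok, 3] - 1L) * dm[1] * dm[2] + (nb[i_ok, 2] - 1L) * dm[1] +
      nb[i_ok, 1]
    j <- pos[nidx]
    hit <- which(j > 0L)
    for (h in hit) {
      ri <- find(i_ok[h])
      rj <- find(j[h])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  list(coords = coords, component = comp)
}

#' Cluster PVS voxels under 26-connectivity
#'
#' Groups PVS voxels into clusters: voxels belong to the same cluster when
#' their faces, edges or corners are in contact. Cluster volume is the voxel
#' count (not mm^3), the convention appropriate when slice thickness exceeds
#' the PVS thickness.
#'
#' @param pvs_mask Logical/0-1 3D array.
#' @return A tibble with one row per cluster: `cluster_id`, `volume_voxels`,
#'   and `voxels` (a list column of n-by-3 integer matrices of 1-based voxel
#'   indices). Empty mask gives a zero-row tibble.
#' @export
cluster_pvs <- function(pvs_mask) {
  lab <- .label_components(pvs_mask)
  if (is.null(lab)) {
    return(tibble::tibble(cluster_id = integer(), volume_voxels = integer(),
                          voxels = list()))
  }
  split_rows <- split(seq_len(nrow(lab$coords)), lab$component)
  vox <- unname(lapply(split_rows, function(r) lab$coords[r, , drop = FALSE]))
  tibble::tibble(
    cluster_id = seq_along(vox),
    volume_voxels = vapply(vox, nrow, integer(1)),
    voxels = vox
  )
}

#' Cluster diameter (mm)
#'
#' For each axial slice the cluster intersects, the in-plane area is the
#' number of cluster voxels in the slice times the in-plane voxel area; its
#' equivalent circular diameter is `2 * sqrt(area / pi)`. The cluster
#' diameter is the maximum over slices — an in-plane measure, because the
#' slice thickness exceeds the PVS thickness.
#'
#' @param voxels n-by-3 matrix of voxel indices (columns x, y, z/slice).
#' @param spacing Voxel size in mm, length 3.
#' @return Diameter in mm.
#' @export
measure_diameter <- function(voxels, spacing) {
  if (is.null(dim(voxels)) || nrow(voxels) == 0) {
    stop("measure_diameter: empty cluster", call. = FALSE)
  }
  per_slice <- table(voxels[, 3])
  area <- max(per_slice) * spacing[1] * spacing[2]
  2 * sqrt(area / pi)
}

#' Assign a cluster to a parcellation region
#'
#' The cluster's region is the majority label over its voxels, ignoring
#' background (label 0); ties break to the smallest label id. A cluster lying
#' entirely on background gets `NA` (such clusters are excluded from region
#' metrics).
#'
#' @param voxels n-by-3 matrix of voxel indices.
#' @param label_map Integer 3D array of region label ids (0 = background).
#' @return A single label id, or `NA_integer_`.
#' @export
assign_region <- function(voxels, label_map) {
  labs <- label_map[voxels]
  labs <- labs[labs > 0]
  if (length(labs) == 0) return(NA_integer_)
  tab <- table(labs)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Annotate clusters with diameter, region and network tags
#'
#' @param clusters Tibble from [cluster_pvs()].
#' @param label_map Integer region label array.
#' @param spacing Voxel size in mm, length 3.
#' @param registry Optional registry from [build_registry()]; when given,
#'   region name, hemisphere and network tags are joined on.
#' @return The cluster tibble with added columns `diameter_mm`,
#'   `region_label`, voxel-index centroids `cx`/`cy`/`cz`, and (with a
#'   registry) `region`, `hemisphere`, `networks`.
#' @export
annotate_clusters <- function(clusters, label_map, spacing, registry = NULL) {
  if (nrow(clusters) == 0) {
    out <- dplyr::mutate(clusters, diameter_mm = numeric(0),
                         region_label = integer(0), cx = numeric(0),
                         cy = numeric(0), cz = numeric(0))
    if (!is.null(registry)) {
      out <- dplyr::mutate(out, region = character(0),
                           hemisphere = character(0), networks = character(0))
    }
    return(out)
  }
  out <- clusters |>
    dplyr::mutate(
      diameter_mm = vapply(.data$voxels, measure_diameter, numeric(1),
                           spacing = spacing),
      region_label = vapply(.data$voxels, assign_region, integer(1),
                            label_map = label_map),
      cx = vapply(.data$voxels, function(v) mean(v[, 1]), numeric(1)),
      cy = vapply(.data$voxels, function(v) mean(v[, 2]), numeric(1)),
      cz = vapply(.data$voxels, function(v) mean(v[, 3]), numeric(1))
    )
  if (!is.null(registry)) {
    key <- registry[, c("label_id", "name", "hemisphere", "networks")]
    names(key) <- c("region_label", "region", "hemisphere", "networks")
    out <- dplyr::left_join(out, key, by = "region_label")
  }
  out
}
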