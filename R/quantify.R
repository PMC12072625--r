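# Roll clusters up into per-region and per-network metric tables, with
# region-size normalizations and the Potter visual score.

#' Per-region PVS metrics
#'
#' One row per registry region (zero-filled when a region has no clusters):
#' PVS count, total PVS volume in voxels, mean cluster diameter (0 when the
#' region has no clusters), the region's voxel count from the label map, and
#' the region-size normalizations `volume_fraction = pvs_volume_voxels /
#' region_voxels` and `count_fraction = pvs_count / region_voxels`. With the
#' strict 72-area registry this yields the subject's 288 data points
#' (72 regions x 4 variables: count, volume, diameter, WM volume).
#'
#' Clusters assigned to background (`region_label` `NA`) are dropped with a
#' message; a cluster carrying a label absent from the registry is an error
#' naming the label.
#'
#' @param clusters Annotated cluster tibble (see [annotate_clusters()]) with
#'   columns `region_label`, `volume_voxels`, `diameter_mm`.
#' @param label_map Integer region label array (0 = background).
#' @param registry Registry tibble from [build_registry()].
#' @return A tibble with one row per registry region.
#' @export
quantify_regions <- function(clusters, label_map, registry) {
  on_bg <- is.na(clusters$region_label)
  if (any(on_bg)) {
    message(sum(on_bg), " cluster(s) entirely on background excluded from ",
            "region metrics")
    clusters <- clusters[!on_bg, ]
  }
  unknown <- setdiff(unique(clusters$region_label), registry$label_id)
  if (length(unknown) > 0) {
    stop("cluster(s) assigned to label(s) absent from the registry: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  region_voxels <- vapply(registry$label_id,
                          function(id) sum(label_map == id), numeric(1))
  per_region <- clusters |>
    dplyr::group_by(label_id = .data$region_label) |>
    dplyr::summarise(pvs_count = dplyr::n(),
                     pvs_volume_voxels = sum(.data$volume_voxels),
                     pvs_diameter_mm = mean(.data$diameter_mm),
                     .groups = "drop")
  out <- registry |>
    dplyr::mutate(region_voxels = as.integer(region_voxels)) |>
    dplyr::left_join(per_region, by = "label_id") |>
    dplyr::mutate(
      pvs_count = dplyr::coalesce(.data$pvs_count, 0L),
      pvs_volume_voxels = as.integer(
        dplyr::coalesce(.data$pvs_volume_voxels, 0L)),
      pvs_diameter_mm = dplyr::coalesce(.data$pvs_diameter_mm, 0),
      volume_fraction = ifelse(.data$region_voxels > 0,
                               .data$pvs_volume_voxels / .data$region_voxels,
                               0),
      count_fraction = ifelse(.data$region_voxels > 0,
                              .data$pvs_count / .data$region_voxels, 0)
    ) |>
    dplyr::select("label_id", "name", "hemisphere", "group", "networks",
                  "pvs_count", "pvs_volume_voxels", "pvs_diameter_mm",
                  "region_voxels", "volume_fraction", "count_fraction")
  tibble::as_tibble(out)
}

#' Aggregate region metrics into network metrics
#'
#' Sums counts and volumes of each network's member regions per hemisphere;
#' the network diameter is the cluster-count-weighted mean of member-region
#' diameters (so regions holding more PVSs weigh their typical size
#' accordingly; 0 when the network holds no clusters). Regions belonging to
#' no analyzed network contribute to none. Always returns the full 3 networks
#' x 2 sides = 6 rows.
#'
#' @param region_metrics Tibble from [quantify_regions()]; must cover every
#'   registry region.
#' @param registry Registry tibble.
#' @return A tibble with columns `network`, `side`, `pvs_count`,
#'   `pvs_volume_voxels`, `pvs_diameter_mm`.
#' @export
aggregate_networks <- function(region_metrics, registry) {
  missing_ids <- setdiff(registry$label_id, region_metrics$label_id)
  if (length(missing_ids) > 0) {
    stop("region metrics do not cover registry label(s): ",
         paste(sort(missing_ids), collapse = ", "), call. = FALSE)
  }
  long <- .registry_network_long(registry) |>
    dplyr::left_join(region_metrics[, c("label_id", "pvs_count",
                                        "pvs_volume_voxels",
                                        "pvs_diameter_mm")],
                     by = "label_id") |>
    dplyr::group_by(.data$network, side = .data$hemisphere) |>
    dplyr::summarise(
      total_count = sum(.data$pvs_count),
      total_volume = sum(.data$pvs_volume_voxels),
      mean_diameter = ifelse(sum(.data$pvs_count) > 0,
                             stats::weighted.mean(.data$pvs_diameter_mm,
                                                  .data$pvs_count), 0),
      .groups = "drop"
    ) |>
    dplyr::rename(pvs_count = "total_count",
                  pvs_volume_voxels = "total_volume",
                  pvs_diameter_mm = "mean_diameter")
  grid <- tidyr::expand_grid(network = .pvs_networks, side = .pvs_sides)
  grid |>
    dplyr::left_join(long, by = c("network", "side")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("pvs_"),
                                ~ dplyr::coalesce(.x, 0)))
}

#' Potter visual rating of PVS burden
#'
#' Ordinal 0--4 score by PVS count: 0 when no PVS is visible, 1 for 1--10,
#' 2 for 11--20, 3 for 21--40, and 4 for more than 40. By default the scoring
#' unit is a whole scoring zone's count (e.g. whole-brain white matter); the
#' function is vectorized so it can equally be applied per region.
#'
#' @param pvs_count Non-negative integer count(s).
#' @return Integer score(s) in 0--4.
#' @examples
#' potter_score(c(0, 10, 11, 40, 41))
#' @export
potter_score <- function(pvs_count) {
  if (any(!is.finite(pvs_count)) || any(pvs_count < 0) ||
      any(pvs_count %% 1 != 0)) {
    stop("`pvs_count` must be non-negative whole number(s)", call. = FALSE)
  }
  score <- integer(length(pvs_count))
  score[pvs_count >= 1 & pvs_count <= 10] <- 1L
  score[pvs_count >= 11 & pvs_count <= 20] <- 2L
  score[pvs_count >= 21 & pvs_count <= 40] <- 3L
  score[pvs_count > 40] <- 4L
  score
}

#' Correlate visual scores with quantitative counts
#'
#' Spearman rank correlation (average ranks for ties) between per-subject
#' quantitative PVS counts and their visual scores.
#'
#' @param counts Numeric vector of quantitative counts.
#' @param scores Numeric vector of visual scores, same length.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
compare_visual_vs_quantitative <- function(counts, scores) {
  if (length(counts) != length(scores)) {
    stop("`counts` and `scores` must have the same length", call. = FALSE)
  }
  if (length(counts) < 3) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(counts) == 0 || stats::sd(scores) == 0) {
    stop("rank correlation is undefined for a constant input vector",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(counts, scores, method = "spearman",
                                         exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(counts))
}

#' Full per-subject quantification
#'
#' Combines region metrics, network metrics, and the white-matter
#' normalization: `wm_normalized_pvs_volume` is the total number of PVS
#' voxels inside the WM mask divided by the WM voxel count.
#'
#' @param pvs_mask Logical PVS mask array.
#' @param clusters Annotated cluster tibble.
#' @param label_map Integer region label array.
#' @param wm_mask Logical white-matter mask.
#' @param registry Registry tibble.
#' @return A list of class `pvs_quantification` with elements `regions`,
#'   `networks`, `wm_volume_voxels`, `wm_normalized_pvs_volume`.
#' @export
quantify_subject <- function(pvs_mask, clusters, label_map, wm_mask,
                             registry) {
  regions <- quantify_regions(clusters, label_map, registry)
  networks <- aggregate_networks(regions, registry)
  wm_vox <- sum(wm_mask != 0)
  wm_pvs <- sum(pvs_mask & (wm_mask != 0))
  structure(
    list(regions = regions, networks = networks,
         wm_volume_voxels = as.integer(wm_vox),
         wm_normalized_pvs_volume = if (wm_vox > 0) wm_pvs / wm_vox else 0),
    class = "pvs_quantification"
  )
}

#' @export
print.pvs_quantification <- function(x, ...) {
  cat("<pvs_quantification> ", nrow(x$regions), " regions, ",
      sum(x$regions$pvs_count), " clusters, WM-normalized PVS volume ",
      signif(x$wm_normalized_pvs_volume, 4), "\n", sep = "")
  invisible(x)
}
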