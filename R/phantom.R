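# Synthetic phantom MRI: co-registered anisotropic volumes with inserted
# tubular hyperintense PVS structures and voxel-level ground truth.

# Ellipsoid membership test in physical mm coordinates.
.in_ellipsoid <- function(X, center, semi) {
  rowSums(sweep(sweep(X, 2, center, "-"), 2, semi, "/")^2) <= 1
}

# mm coordinates of all voxel centers, n-by-3.
.voxel_centers <- function(shape, spacing) {
  as.matrix(expand.grid(.axis_mm(shape[1], spacing[1]),
                        .axis_mm(shape[2], spacing[2]),
                        .axis_mm(shape[3], spacing[3])))
}

# Voronoi label assignment: nearest seed in mm, seeds is k-by-3.
.nearest_seed <- function(X, seeds) {
  d2 <- matrix(0, nrow(X), nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    d2[, k] <- (X[, 1] - seeds[k, 1])^2 + (X[, 2] - seeds[k, 2])^2 +
      (X[, 3] - seeds[k, 3])^2
  }
  max.col(-d2, ties.method = "first")
}

#' Generate a phantom with ground-truth PVS tubes
#'
#' Builds a co-registered synthetic "subject": a T2-like intensity volume, a
#' region label map, white-matter (WM) and basal-ganglia (BG) masks, and a
#' ground-truth table of inserted tubular PVS structures.
#'
#' Geometry: the brain is an ellipsoid inside the grid; two smaller
#' ellipsoids (one per hemisphere) form the BG; WM is the remainder of the
#' brain. Each hemisphere's WM is partitioned into the registry's cortical
#' regions, and each BG blob into its four nuclei, by nearest-seed (Voronoi)
#' assignment over seeds drawn inside the respective masks. The background
#' intensity is a per-region constant (base plus a small region-dependent
#' offset) optionally multiplied by a smooth low-frequency bias field;
#' Gaussian noise is added last.
#'
#' Tubes are rasterized in physical mm with the anisotropic spacing: a voxel
#' belongs to a tube when its center lies within `radius_mm` of the tube's
#' axis segment. Tubes are thin relative to the slice thickness, so their
#' voxel volume is counted in voxels, not mm^3. By construction tubes are
#' pairwise non-adjacent under 26-connectivity, 26-connected within
#' themselves, strictly interior to the grid, and every tube voxel keeps a
#' majority of non-tube surrounding voxels (at most 9 of its 26 neighbors
#' belong to the same tube), which is what makes a thin hyperintense
#' structure stand out in a local-contrast map.
#'
#' @param shape Grid dimensions in voxels, length 3.
#' @param spacing Voxel size in mm; default `c(0.8, 0.8, 4.4)` (thick axial
#'   slices).
#' @param n_pvs Number of tubes to insert.
#' @param radius_mm,length_mm Ranges (length 2) the tube radius/length are
#'   drawn from, uniformly, in mm.
#' @param contrast Intensity elevation of tube voxels above the local
#'   background.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for a
#'   noiseless phantom).
#' @param bias_amplitude Relative amplitude of the multiplicative
#'   low-frequency bias field (0 disables it).
#' @param base_intensity Background parenchyma intensity.
#' @param registry Region registry; the default analysis set labels 38
#'   regions per hemisphere.
#' @param seed Integer seed; fixes all randomness.
#' @param max_tries Placement attempts per tube before giving up.
#' @return An object of class `pvs_phantom`: a list with `t2`, `background`,
#'   `labels`, `wm_mask`, `bg_mask`, `spacing`, `truth` (tibble: `pvs_id`,
#'   `seed_region`, `n_voxels`, `contrast`, centroid indices, `voxels` list
#'   column), `registry` and `params`.
#' @export
generate_phantom <- function(shape = c(64, 64, 16),
                             spacing = c(0.8, 0.8, 4.4),
                             n_pvs = 30,
                             radius_mm = c(0.3, 0.7),
                             length_mm = c(2, 7),
                             contrast = 120,
                             noise_sd = 5,
                             bias_amplitude = 0,
                             base_intensity = 100,
                             registry = build_registry("analysis"),
                             seed = 1L,
                             max_tries = 200L) {
  stopifnot(length(shape) == 3, length(spacing) == 3, all(spacing > 0),
            n_pvs >= 0, all(radius_mm > 0), all(length_mm > 0),
            contrast > 0, noise_sd >= 0)
  shape <- as.integer(shape)
  withr::with_seed(as.integer(seed), {
    extent <- shape * spacing
    center <- extent / 2
    X <- .voxel_centers(shape, spacing)

    brain <- .in_ellipsoid(X, center, 0.47 * extent)
    bg_l <- .in_ellipsoid(X, center - c(0.18 * extent[1], 0, 0),
                          c(0.10, 0.12, 0.15) * extent)
    bg_r <- .in_ellipsoid(X, center + c(0.18 * extent[1], 0, 0),
                          c(0.10, 0.12, 0.15) * extent)
    bg <- (bg_l | bg_r) & brain
    wm <- brain & !bg
    left <- X[, 1] < center[1]

    labels_flat <- integer(nrow(X))
    for (side in c("left", "right")) {
      side_sel <- if (side == "left") left else !left
      hemi_reg <- registry[registry$hemisphere == side, ]
      ctx_reg <- hemi_reg[hemi_reg$group != "basal_ganglia", ]
      bgn_reg <- hemi_reg[hemi_reg$group == "basal_ganglia", ]

      wm_idx <- which(wm & side_sel)
      if (length(wm_idx) < nrow(ctx_reg)) {
        stop("phantom too small to seed every cortical region", call. = FALSE)
      }
      seeds <- X[sample(wm_idx, nrow(ctx_reg)), , drop = FALSE]
      labels_flat[wm_idx] <-
        ctx_reg$label_id[.nearest_seed(X[wm_idx, , drop = FALSE], seeds)]

      bg_idx <- which(bg & side_sel)
      if (nrow(bgn_reg) > 0 && length(bg_idx) >= nrow(bgn_reg)) {
        seeds <- X[sample(bg_idx, nrow(bgn_reg)), , drop = FALSE]
        labels_flat[bg_idx] <-
          bgn_reg$label_id[.nearest_seed(X[bg_idx, , drop = FALSE], seeds)]
      }
    }

    labels <- array(labels_flat, shape)
    wm_mask <- array(wm, shape)
    bg_mask <- array(bg, shape)

    truth <- .place_tubes(shape, spacing, wm_mask | bg_mask, n_pvs,
                          radius_mm, length_mm, contrast, max_tries)
    if (nrow(truth) > 0) {
      truth$seed_region <- as.integer(labels[truth$mid_lin])
      truth$mid_lin <- NULL
    }

    # per-region constant offsets in [-2, 2], deterministic in the label id
    offset_of <- function(l) ifelse(l > 0, (((l * 7) %% 11) - 5) * 0.4, 0)
    background <- array(ifelse(labels_flat > 0,
                               base_intensity + offset_of(labels_flat),
                               ifelse(brain, base_intensity, 40)), shape)
    if (bias_amplitude > 0) {
      bias <- 1 + bias_amplitude *
        (0.7 * (2 * (X[, 1] / extent[1] - 0.5)) +
           0.3 * cos(pi * X[, 3] / extent[3]))
      background <- background * array(bias, shape)
    }

    t2 <- background
    for (v in truth$voxels) t2[v] <- t2[v] + contrast
    if (noise_sd > 0) {
      t2 <- t2 + array(stats::rnorm(length(t2), 0, noise_sd), shape)
    }

    structure(
      list(t2 = t2, background = background, labels = labels,
           wm_mask = wm_mask, bg_mask = bg_mask, spacing = spacing,
           truth = truth, registry = registry,
           params = list(shape = shape, spacing = spacing, n_pvs = n_pvs,
                         radius_mm = radius_mm, length_mm = length_mm,
                         contrast = contrast, noise_sd = noise_sd,
                         bias_amplitude = bias_amplitude,
                         base_intensity = base_intensity, seed = seed)),
      class = "pvs_phantom"
    )
  })
}

# Place n_pvs pairwise non-adjacent tubes inside `allowed`. Returns the
# ground-truth tibble. Each accepted tube is 26-connected, strictly interior
# to the grid, and no tube voxel has more than 9 same-tube neighbors.
.place_tubes <- function(shape, spacing, allowed, n_pvs, radius_mm, length_mm,
                         contrast, max_tries) {
  empty <- tibble::tibble(pvs_id = integer(), seed_region = integer(),
                          n_voxels = integer(), contrast = numeric(),
                          cx = numeric(), cy = numeric(), cz = numeric(),
                          voxels = list())
  if (n_pvs == 0) return(empty)

  blocked <- array(FALSE, shape)
  allowed_idx <- which(allowed)
  if (length(allowed_idx) == 0) {
    stop("phantom masks are empty; cannot place tubes", call. = FALSE)
  }
  rows <- vector("list", n_pvs)
  placed <- 0L
  for (tube in seq_len(n_pvs)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      mid_i <- arrayInd(sample(allowed_idx, 1), shape)
      mid <- (as.numeric(mid_i) - 0.5) * spacing
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      L <- stats::runif(1, length_mm[1], length_mm[2])
      r <- stats::runif(1, radius_mm[1], radius_mm[2])
      vox <- .rasterize_tube(shape, spacing, mid, u, L, r)
      if (is.null(vox) || nrow(vox) == 0) next
      # strictly interior (full 26-neighborhoods exist everywhere)
      if (any(vox == 1L) ||
          any(sweep(vox, 2, shape, ">=") & TRUE)) next
      lin <- (vox[, 3] - 1L) * shape[1] * shape[2] +
        (vox[, 2] - 1L) * shape[1] + vox[, 1]
      if (!all(allowed[lin])) next
      if (any(blocked[lin])) next
      if (!.is_connected26(vox)) next
      if (max(.self_neighbor_counts(vox)) > 9) next

      # accept: mark tube and its 1-voxel dilation as blocked
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        nb <- sweep(vox, 2, c(dx, dy, dz), "+")
        keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
        nbl <- (nb[keep, 3] - 1L) * shape[1] * shape[2] +
          (nb[keep, 2] - 1L) * shape[1] + nb[keep, 1]
        blocked[nbl] <- TRUE
      }
      placed <- placed + 1L
      rows[[placed]] <- tibble::tibble(
        pvs_id = placed,
        seed_region = NA_integer_,  # filled by caller's label map below
        n_voxels = nrow(vox), contrast = contrast,
        cx = mean(vox[, 1]), cy = mean(vox[, 2]), cz = mean(vox[, 3]),
        voxels = list(vox),
        mid_lin = lin[1]
      )
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place ", n_pvs, " non-touching tubes (placed ", placed,
           "); enlarge the grid or reduce n_pvs", call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

# Voxels whose center lies within radius r of the axis segment through `mid`
# with direction u and length L (all mm). Returns an n-by-3 integer matrix.
.rasterize_tube <- function(shape, spacing, mid, u, L, r) {
  p0 <- mid - (L / 2) * u
  p1 <- mid + (L / 2) * u
  lo <- pmin(p0, p1) - r
  hi <- pmax(p0, p1) + r
  i_lo <- pmax(1L, floor(lo / spacing + 0.5))
  i_hi <- pmin(shape, ceiling(hi / spacing + 0.5))
  if (any(i_lo > i_hi)) return(NULL)
  g <- as.matrix(expand.grid(i_lo[1]:i_hi[1], i_lo[2]:i_hi[2],
                             i_lo[3]:i_hi[3]))
  P <- sweep(g - 0.5, 2, spacing, "*")
  v <- p1 - p0
  vv <- sum(v^2)
  W <- sweep(P, 2, p0, "-")
  t <- pmin(pmax((W %*% v) / vv, 0), 1)
  proj <- outer(as.numeric(t), v)
  d2 <- rowSums((W - proj)^2)
  sel <- d2 <= r^2
  if (!any(sel)) return(NULL)
  m <- g[sel, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# 26-connectivity of a small voxel coordinate set, by breadth-first growth
# over Chebyshev-adjacent pairs.
.is_connected26 <- function(vox) {
  n <- nrow(vox)
  if (n <= 1) return(TRUE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    ch <- pmax(abs(vox[(i + 1):n, 1] - vox[i, 1]),
               pmax(abs(vox[(i + 1):n, 2] - vox[i, 2]),
                    abs(vox[(i + 1):n, 3] - vox[i, 3])))
    adj[i, (i + 1):n] <- ch == 1
  }
  adj <- adj | t(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# For each voxel, how many other voxels of the same set are 26-neighbors.
.self_neighbor_counts <- function(vox) {
  n <- nrow(vox)
  if (n == 1) return(0L)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    ch <- pmax(abs(vox[, 1] - vox[i, 1]),
               pmax(abs(vox[, 2] - vox[i, 2]), abs(vox[, 3] - vox[i, 3])))
    cnt[i] <- sum(ch == 1)
  }
  cnt
}

#' @export
print.pvs_phantom <- function(x, ...) {
  cat("<pvs_phantom> ", paste(x$params$shape, collapse = "x"),
      " voxels @ ", paste(x$spacing, collapse = "x"), " mm\n", sep = "")
  cat("  tubes: ", nrow(x$truth), " (contrast ", x$params$contrast,
      ", noise sd ", x$params$noise_sd, ")\n", sep = "")
  cat("  WM voxels: ", sum(x$wm_mask), ", BG voxels: ", sum(x$bg_mask),
      "\n", sep = "")
  invisible(x)
}
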