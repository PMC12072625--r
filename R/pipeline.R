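# Pipeline entry points tying the stages together: simulate phantom + cohort
# to disk, segment volumes from disk, compare a cohort from disk. Each
# command echoes its effective configuration to the output directory so a
# run is reproducible from its artifacts alone. A thin command-line wrapper
# over these functions ships at `system.file("cli", "pvsmap.R", package =
# "pvsmap")`.

.ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  if (file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  invisible(outdir)
}

#' Simulate a phantom and a cohort to disk
#'
#' Writes the phantom volumes as NIfTI (T2-like intensity, region labels, WM
#' and BG masks), the ground-truth tube table and the synthetic cohort as
#' CSV, the registry CSV, and the effective configuration as JSON.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; forwarded to both generators unless the
#'   arguments below override it.
#' @param phantom_args Named list of [generate_phantom()] overrides.
#' @param cohort A [cohort_spec()]; defaults to the study-cohort marginals
#'   with the given seed.
#' @param registry Registry used for phantom labeling.
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(outdir, seed = 1L, phantom_args = list(),
                         cohort = cohort_spec(seed = seed),
                         registry = build_registry("analysis")) {
  .ensure_outdir(outdir)
  args <- utils::modifyList(list(seed = seed, registry = registry),
                            phantom_args)
  ph <- do.call(generate_phantom, args)
  coh <- generate_cohort(cohort)

  paths <- c(
    t2 = file.path(outdir, "phantom_t2.nii.gz"),
    labels = file.path(outdir, "phantom_labels.nii.gz"),
    wm_mask = file.path(outdir, "phantom_wm_mask.nii.gz"),
    bg_mask = file.path(outdir, "phantom_bg_mask.nii.gz"),
    truth = file.path(outdir, "phantom_truth.csv"),
    cohort = file.path(outdir, "cohort.csv"),
    registry = file.path(outdir, "region_registry.csv"),
    config = file.path(outdir, "config.json")
  )
  write_volume(ph$t2, ph$spacing, paths[["t2"]])
  write_volume(ph$labels, ph$spacing, paths[["labels"]], datatype = "int32")
  write_volume(ph$wm_mask, ph$spacing, paths[["wm_mask"]], datatype = "int32")
  write_volume(ph$bg_mask, ph$spacing, paths[["bg_mask"]], datatype = "int32")
  truth_tab <- ph$truth[, setdiff(names(ph$truth), "voxels")]
  readr::write_csv(truth_tab, paths[["truth"]])
  write_cohort(coh, paths[["cohort"]])
  write_registry(registry, paths[["registry"]])

  cfg <- list(
    command = "simulate", seed = seed,
    phantom = ph$params,
    cohort = unclass(cohort)[setdiff(names(cohort), "effects")],
    cohort_effects = if (is.null(cohort$effects)) list() else
      as.list(cohort$effects),
    registry_mode = attr(registry, "registry_mode")
  )
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  message("simulate: ", nrow(ph$truth), " tubes, cohort of ", nrow(coh),
          " subjects, seed ", seed)
  invisible(paths)
}

#' Segment PVS from volumes on disk
#'
#' Reads the T2-like volume, the WM/BG masks and the label map, checks that
#' all share one geometry (a mismatch is an error naming the offending
#' file), segments and clusters PVS voxels, and writes the PVS mask (NIfTI)
#' and the cluster table (CSV).
#'
#' @param t2_path,wm_path,bg_path,labels_path Input NIfTI paths.
#' @param outdir Output directory.
#' @param config A [segmentation_config()].
#' @param registry Registry for region annotation of clusters.
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_segment <- function(t2_path, wm_path, bg_path, labels_path, outdir,
                        config = segmentation_config(),
                        registry = build_registry("analysis")) {
  .ensure_outdir(outdir)
  t2 <- read_volume(t2_path)
  vols <- list(wm = read_volume(wm_path), bg = read_volume(bg_path),
               labels = read_volume(labels_path))
  files <- c(wm = wm_path, bg = bg_path, labels = labels_path)
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]$values), dim(t2$values))) {
      stop("geometry mismatch: ", files[[nm]], " is ",
           paste(dim(vols[[nm]]$values), collapse = "x"), " but ", t2_path,
           " is ", paste(dim(t2$values), collapse = "x"), call. = FALSE)
    }
  }
  mask <- segment_pvs(t2$values, vols$wm$values, vols$bg$values, t2$spacing,
                      config)
  clusters <- cluster_pvs(mask) |>
    annotate_clusters(array(as.integer(round(vols$labels$values)),
                            dim(vols$labels$values)),
                      t2$spacing, registry)

  paths <- c(pvs_mask = file.path(outdir, "pvs_mask.nii.gz"),
             clusters = file.path(outdir, "clusters.csv"),
             config = file.path(outdir, "segment_config.json"))
  write_volume(mask, t2$spacing, paths[["pvs_mask"]], datatype = "int32")
  readr::write_csv(clusters[, setdiff(names(clusters), "voxels")],
                   paths[["clusters"]])
  jsonlite::write_json(
    list(command = "segment", diff_threshold = config$diff_threshold,
         kernel = config$kernel, connectivity = config$connectivity,
         uniformize = config$uniformize, fwhm_mm = config$fwhm_mm,
         registry_mode = attr(registry, "registry_mode")),
    paths[["config"]], auto_unbox = TRUE, digits = NA)
  message("segment: ", nrow(clusters), " clusters, ", sum(mask),
          " PVS voxels (threshold ", config$diff_threshold, ", kernel ",
          config$kernel, ")")
  invisible(paths)
}

#' Compare symptom groups from a cohort on disk
#'
#' Reads a cohort CSV, runs the 18 Mann-Whitney comparisons for one symptom,
#' and writes the results CSV, the severity map as JSON, and (optionally) a
#' rendered severity figure.
#'
#' @param cohort_path Cohort CSV path.
#' @param symptom One of `"language"`, `"sensory"`, `"stereotypies"`,
#'   `"support_level"`; anything else is an error listing the options.
#' @param outdir Output directory.
#' @param alpha Significance level.
#' @param fdr Benjamini-Hochberg correction flag.
#' @param figure Write `severity_map.png`.
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_compare <- function(cohort_path, symptom, outdir, alpha = 0.05,
                        fdr = FALSE, figure = TRUE) {
  if (!is.character(symptom) || length(symptom) != 1 ||
      !symptom %in% .pvs_symptoms) {
    stop("unknown symptom `", paste(symptom, collapse = ","),
         "`; valid options: ", paste(.pvs_symptoms, collapse = ", "),
         call. = FALSE)
  }
  .ensure_outdir(outdir)
  cohort <- read_cohort(cohort_path)
  res <- run_comparisons(cohort, symptom, alpha = alpha, fdr = fdr)
  sev <- severity_map(res)
  message("compare [", symptom, "]: groups low n=",
          attr(res, "n_low", exact = TRUE), ", high n=",
          attr(res, "n_high", exact = TRUE), ", excluded n=",
          attr(res, "n_excluded", exact = TRUE))

  paths <- c(results = file.path(outdir, "comparisons.csv"),
             severity = file.path(outdir, "severity.json"))
  readr::write_csv(tidy(res), paths[["results"]])
  sev_json <- list(
    symptom = symptom, alpha = alpha, fdr = fdr,
    n_low = attr(res, "n_low", exact = TRUE),
    n_high = attr(res, "n_high", exact = TRUE),
    n_excluded = attr(res, "n_excluded", exact = TRUE),
    cells = as.list(tibble::as_tibble(sev))
  )
  jsonlite::write_json(sev_json, paths[["severity"]], auto_unbox = TRUE,
                       digits = NA)
  if (figure) {
    fig_path <- file.path(outdir, "severity_map.png")
    ggplot2::ggsave(fig_path, autoplot(sev), width = 5, height = 3.5,
                    dpi = 150)
    paths <- c(paths, figure = fig_path)
  }
  invisible(paths)
}

#' Run the full pipeline
#'
#' simulate -> segment -> quantify -> compare on one output directory.
#'
#' @inheritParams cmd_simulate
#' @inheritParams cmd_compare
#' @param config Segmentation configuration.
#' @return Named character vector of all written paths, invisibly.
#' @export
cmd_all <- function(outdir, seed = 1L, symptom = "language",
                    config = segmentation_config(), alpha = 0.05,
                    fdr = FALSE) {
  sim <- cmd_simulate(outdir, seed = seed)
  seg <- cmd_segment(sim[["t2"]], sim[["wm_mask"]], sim[["bg_mask"]],
                     sim[["labels"]], outdir, config = config)
  cmp <- cmd_compare(sim[["cohort"]], symptom, outdir, alpha = alpha,
                     fdr = fdr)
  invisible(c(sim, seg, cmp))
}

#' Read pipeline outputs back
#'
#' Readers for the CSV/JSON artifacts the pipeline writes; values round-trip
#' losslessly.
#'
#' @param path File path.
#' @return `read_clusters()` and `read_comparisons()` return tibbles;
#'   `read_severity()` a list.
#' @export
read_clusters <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_clusters
#' @export
read_comparisons <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    network = readr::col_character(),
                    side = readr::col_character(),
                    measure = readr::col_character(),
                    significant = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' @rdname read_clusters
#' @export
read_severity <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
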