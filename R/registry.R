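# Cortical and basal-ganglia areas, per hemisphere, in listing order within
# lobe/group. Names follow DKT-style parcellation labels.
.pvs_area_table <- function() {
  tibble::tribble(
    ~name,                        ~group,
    "entorhinal",                 "temporal",
    "parahippocampal",            "temporal",
    "fusiform",                   "temporal",
    "superior_temporal",          "temporal",
    "middle_temporal",            "temporal",
    "inferior_temporal",          "temporal",
    "transverse_temporal",        "temporal",
    "temporal_pole",              "temporal",
    "superior_frontal",           "frontal",
    "rostral_middle_frontal",     "frontal",
    "caudal_middle_frontal",      "frontal",
    "pars_opercularis",           "frontal",
    "pars_triangularis",          "frontal",
    "pars_orbitalis",             "frontal",
    "lateral_orbitofrontal",      "frontal",
    "medial_orbitofrontal",       "frontal",
    "precentral",                 "frontal",
    "paracentral",                "frontal",
    "frontal_pole",               "frontal",
    "postcentral",                "parietal",
    "supramarginal",              "parietal",
    "superior_parietal",          "parietal",
    "inferior_parietal",          "parietal",
    "precuneus",                  "parietal",
    "lingual",                    "occipital",
    "pericalcarine",              "occipital",
    "cuneus",                     "occipital",
    "lateral_occipital",          "occipital",
    "rostral_anterior_cingulate", "cingulate",
    "caudal_anterior_cingulate",  "cingulate",
    "posterior_cingulate",        "cingulate",
    "isthmus_cingulate",          "cingulate",
    "thalamus",                   "basal_ganglia",
    "caudate",                    "basal_ganglia",
    "putamen",                    "basal_ganglia",
    "pallidum",                   "basal_ganglia"
  )
}

# Network key regions. The angular gyrus carries the DMN's inferior-parietal
# territory under its own label so that inferior_parietal can stay a CEN/FPN
# member and the two networks remain disjoint; the insula (SN) is likewise an
# additional labeled region on top of the 72-area listing.
.pvs_network_table <- function() {
  list(
    DMN     = c("angular_gyrus", "medial_orbitofrontal", "middle_temporal",
                "posterior_cingulate", "precuneus"),
    CEN_FPN = c("caudal_anterior_cingulate", "inferior_parietal",
                "inferior_temporal", "lateral_orbitofrontal", "caudate",
                "rostral_middle_frontal"),
    SN      = c("insula", "rostral_anterior_cingulate")
  )
}

#' Build the region registry
#'
#' Constructs the registry of brain areas in which perivascular spaces (PVS)
#' are mapped: 36 areas per hemisphere (8 temporal, 11 frontal, 5 parietal,
#' 4 occipital, 4 cingulate, 4 basal ganglia), plus, in `"analysis"` mode,
#' two additional labeled regions per hemisphere that carry network
#' memberships not representable inside the 72-area listing: the insula
#' (salience network) and the angular gyrus (default mode network; a distinct
#' label so that the inferior parietal lobule can remain a key region of the
#' central executive / frontoparietal network and the two networks stay
#' disjoint).
#'
#' Label ids are stable: left hemisphere 1--36 (insula 37, angular gyrus 38),
#' right hemisphere 101--136 (137, 138); 0 is reserved for background. Rows
#' are ordered hemisphere-major (left, then right), then by label id, which
#' follows the group order temporal, frontal, parietal, occipital, cingulate,
#' basal ganglia and the listing order within each group.
#'
#' @param mode `"analysis"` (default) returns the full 76-region analysis
#'   set; `"strict_72"` returns exactly the 72-area listing (network columns
#'   then omit the insula/angular memberships carried by the extra labels).
#' @return A tibble with one row per region and columns `name`,
#'   `hemisphere` (`"left"`/`"right"`), `group`, `label_id`, and `networks`
#'   (semicolon-joined subset of `"DMN"`, `"CEN_FPN"`, `"SN"`; `""` when the
#'   region belongs to no analyzed network).
#' @examples
#' reg <- build_registry()
#' nrow(build_registry("strict_72"))
#' regions_in_network(reg, "SN", "right")
#' @export
build_registry <- function(mode = c("analysis", "strict_72")) {
  mode <- match.arg(mode)
  base <- .pvs_area_table()
  extra <- tibble::tibble(
    name = c("insula", "angular_gyrus"),
    group = c("insula", "parietal")
  )
  per_hemi <- dplyr::bind_rows(base, extra)
  nets <- .pvs_network_table()
  net_of <- function(name) {
    member <- vapply(nets, function(m) name %in% m, logical(1))
    paste(names(nets)[member], collapse = ";")
  }
  per_hemi$networks <- unname(vapply(per_hemi$name, net_of, character(1)))

  one_side <- function(side, offset) {
    out <- per_hemi
    out$hemisphere <- side
    out$label_id <- offset + seq_len(nrow(out))
    out
  }
  reg <- dplyr::bind_rows(one_side("left", 0L), one_side("right", 100L))
  reg <- reg[, c("name", "hemisphere", "group", "label_id", "networks")]
  if (mode == "strict_72") {
    reg <- reg[!reg$name %in% c("insula", "angular_gyrus"), ]
  }
  attr(reg, "registry_mode") <- mode
  tibble::as_tibble(reg)
}

#' Member regions of a cognitive network
#'
#' @param registry A registry tibble from [build_registry()].
#' @param network One of `"DMN"`, `"CEN_FPN"`, `"SN"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return The member rows of `registry`, in registry order.
#' @export
regions_in_network <- function(registry, network, hemisphere) {
  if (!is.character(network) || length(network) != 1 ||
      !network %in% c("DMN", "CEN_FPN", "SN")) {
    stop("`network` must be one of \"DMN\", \"CEN_FPN\", \"SN\"", call. = FALSE)
  }
  if (!is.character(hemisphere) || length(hemisphere) != 1 ||
      !hemisphere %in% c("left", "right")) {
    stop("`hemisphere` must be \"left\" or \"right\"", call. = FALSE)
  }
  hemi <- hemisphere
  registry |>
    dplyr::filter(.data$hemisphere == hemi) |>
    dplyr::filter(vapply(strsplit(.data$networks, ";", fixed = TRUE),
                         function(x) network %in% x, logical(1)))
}

#' Write / read a registry CSV
#'
#' The on-disk form has columns `name, hemisphere, group, label_id, networks`
#' with network memberships semicolon-joined; [read_registry()] recovers the
#' tibble losslessly. A copy of the analysis-set registry ships with the
#' package at `system.file("extdata", "region_registry.csv", package =
#' "pvsmap")`.
#'
#' @param registry A registry tibble.
#' @param path File path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the registry tibble.
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    hemisphere = readr::col_character(),
    group = readr::col_character(),
    label_id = readr::col_integer(),
    networks = readr::col_character()
  ), na = character()) |>
    dplyr::mutate(networks = dplyr::coalesce(.data$networks, ""))
}

# Split the semicolon-joined networks column into a long (label_id, network)
# table; regions with no membership drop out.
.registry_network_long <- function(registry) {
  registry |>
    dplyr::filter(.data$networks != "") |>
    dplyr::mutate(network = strsplit(.data$networks, ";", fixed = TRUE)) |>
    tidyr::unnest("network") |>
    dplyr::select("label_id", "name", "hemisphere", "network")
}
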