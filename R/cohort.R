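# Synthetic subject cohorts: categorical marginals reproduced exactly, plus
# per-(network, side) PVS burden metrics with configurable group effects.

.pvs_networks <- c("DMN", "CEN_FPN", "SN")
.pvs_sides <- c("left", "right")
.pvs_measures <- c("count", "volume", "diameter")
.pvs_symptoms <- c("language", "sensory", "stereotypies", "support_level")

# Extreme-of-outcome split presets: which category is the low- and which the
# high-severity group; everything else (intermediate / unknown) is excluded.
.split_presets <- list(
  language = list(field = "language", low = "none_low", high = "absent"),
  sensory = list(field = "sensory", low = "no", high = "yes"),
  stereotypies = list(field = "stereotypies", low = "no", high = "yes"),
  support_level = list(field = "support_level", low = "1", high = "3")
)

#' Cohort specification
#'
#' Describes a synthetic cohort: exact categorical marginals (defaults
#' reproduce the study cohort: 36 subjects, 22 male / 14 female; language
#' impairment 17 none-or-low / 4 intermediate / 15 absent language; sensory
#' disturbances 20 yes / 13 no / 3 unknown; motor stereotypies 17 / 16 / 3
#' unknown; support level 10 / 6 / 20), the baseline distributions of the
#' per-(network, side) PVS metrics, a male elevation of PVS volume, and
#' optional injected group effects.
#'
#' Baseline metrics per (network, side): PVS count is Poisson with mean
#' `count_rate_per_region` times the number of member regions (5 DMN, 6
#' CEN/FPN, 2 SN); volume in voxels is the count times a lognormal mean
#' cluster size; diameter is lognormal in mm. All three are 0 when the count
#' is 0. `sex_effect` multiplies male volumes by `1 + sex_effect` (0 =
#' no sex difference). `effects` injects a location shift into the
#' high-severity group of `effect_symptom`: for each row
#' `(network, side, measure, shift_sd)` the affected column is shifted by
#' `shift_sd` baseline standard deviations.
#'
#' @param n_subjects Number of subjects.
#' @param sex,language,sensory,stereotypies,support Named integer marginals;
#'   each must sum to `n_subjects`.
#' @param age_mean,age_sd,age_range Age distribution (years); normal,
#'   truncated to the range.
#' @param count_rate_per_region Poisson PVS rate per member region.
#' @param cluster_size_meanlog,cluster_size_sdlog Lognormal mean cluster size
#'   (voxels per PVS).
#' @param diameter_meanlog,diameter_sdlog Lognormal PVS diameter (mm).
#' @param wm_meanlog,wm_sdlog Lognormal white-matter volume (voxels).
#' @param sex_effect Fractional male elevation of PVS volume (0 disables).
#' @param effects `NULL`, or a data frame with columns `network`, `side`,
#'   `measure`, `shift_sd`.
#' @param effect_symptom Symptom whose high-severity group receives
#'   `effects`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `pvs_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 36,
                        sex = c(M = 22, F = 14),
                        language = c(none_low = 17, intermediate = 4,
                                     absent = 15),
                        sensory = c(yes = 20, no = 13, unknown = 3),
                        stereotypies = c(yes = 17, no = 16, unknown = 3),
                        support = c(`1` = 10, `2` = 6, `3` = 20),
                        age_mean = 4, age_sd = 2.3, age_range = c(1, 9),
                        count_rate_per_region = 4,
                        cluster_size_meanlog = log(9),
                        cluster_size_sdlog = 0.35,
                        diameter_meanlog = log(1.3), diameter_sdlog = 0.2,
                        wm_meanlog = log(3e5), wm_sdlog = 0.08,
                        sex_effect = 0.35,
                        effects = NULL,
                        effect_symptom = "language",
                        seed = 1L) {
  marg <- list(sex = sex, language = language, sensory = sensory,
               stereotypies = stereotypies, support = support)
  for (nm in names(marg)) {
    m <- marg[[nm]]
    if (any(m < 0) || sum(m) != n_subjects) {
      stop("marginal `", nm, "` must be non-negative and sum to n_subjects (",
           n_subjects, "), got sum ", sum(m), call. = FALSE)
    }
  }
  if (!effect_symptom %in% .pvs_symptoms) {
    stop("`effect_symptom` must be one of: ",
         paste(.pvs_symptoms, collapse = ", "), call. = FALSE)
  }
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    need <- c("network", "side", "measure", "shift_sd")
    if (!all(need %in% names(effects))) {
      stop("`effects` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bad <- !(effects$network %in% .pvs_networks) |
      !(effects$side %in% .pvs_sides) |
      !(effects$measure %in% .pvs_measures)
    if (any(bad)) stop("`effects` contains unknown network/side/measure",
                       call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sex = sex, language = language,
         sensory = sensory, stereotypies = stereotypies, support = support,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         count_rate_per_region = count_rate_per_region,
         cluster_size_meanlog = cluster_size_meanlog,
         cluster_size_sdlog = cluster_size_sdlog,
         diameter_meanlog = diameter_meanlog,
         diameter_sdlog = diameter_sdlog,
         wm_meanlog = wm_meanlog, wm_sdlog = wm_sdlog,
         sex_effect = sex_effect, effects = effects,
         effect_symptom = effect_symptom, seed = as.integer(seed)),
    class = "pvs_cohort_spec"
  )
}

# Draw a category column whose counts equal the marginal exactly. Categories
# named "unknown" are pinned to the last subjects (deterministic placement of
# the n.k. records); everything else is randomly permuted.
.assign_category <- function(marginal, n) {
  vals <- rep(names(marginal), marginal)
  if ("unknown" %in% names(marginal)) {
    k <- marginal[["unknown"]]
    known <- vals[vals != "unknown"]
    c(sample(known), rep("unknown", k))
  } else {
    sample(vals)
  }
}

#' Generate a synthetic cohort
#'
#' Produces one record per subject: demographic/symptom categories whose
#' counts match the spec marginals exactly (not just in expectation), a
#' white-matter volume, and the 18 PVS burden metrics, one per
#' (network, side, measure) with networks DMN, CEN_FPN, SN, sides left/right
#' and measures count, volume (voxels), diameter (mm). Unknown symptom values
#' are assigned to the last subjects in enrollment order. With `effects =
#' NULL` and `sex_effect = 0` the metric distributions are identical in law
#' across every symptom split (a null cohort).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `pvs_cohort` with columns `subject_id`, `sex`,
#'   `age_years`, `language`, `sensory`, `stereotypies`, `support_level`,
#'   `wm_volume_voxels`, and `<network>_<side>_<measure>` metric columns.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' table(cohort$sex)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "pvs_cohort_spec"))
  n <- spec$n_subjects
  withr::with_seed(spec$seed, {
    cohort <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = .assign_category(spec$sex, n),
      age_years = round(pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                                  spec$age_range[1]), spec$age_range[2]), 1),
      language = .assign_category(spec$language, n),
      sensory = .assign_category(spec$sensory, n),
      stereotypies = .assign_category(spec$stereotypies, n),
      support_level = as.integer(.assign_category(spec$support, n)),
      wm_volume_voxels = round(stats::rlnorm(n, spec$wm_meanlog, spec$wm_sdlog))
    )

    n_regions <- c(DMN = 5, CEN_FPN = 6, SN = 2)
    for (net in .pvs_networks) {
      for (side in .pvs_sides) {
        cnt <- stats::rpois(n, spec$count_rate_per_region * n_regions[[net]])
        vol <- round(cnt * stats::rlnorm(n, spec$cluster_size_meanlog,
                                         spec$cluster_size_sdlog))
        dia <- ifelse(cnt > 0,
                      stats::rlnorm(n, spec$diameter_meanlog,
                                    spec$diameter_sdlog), 0)
        vol[cnt == 0] <- 0
        if (spec$sex_effect != 0) {
          male <- cohort$sex == "M"
          vol[male] <- round(vol[male] * (1 + spec$sex_effect))
        }
        cohort[[paste(net, side, "count", sep = "_")]] <- cnt
        cohort[[paste(net, side, "volume", sep = "_")]] <- vol
        cohort[[paste(net, side, "diameter", sep = "_")]] <- round(dia, 3)
      }
    }

    if (!is.null(spec$effects) && nrow(spec$effects) > 0) {
      preset <- .split_presets[[spec$effect_symptom]]
      field <- as.character(cohort[[preset$field]])
      high <- field == preset$high
      for (r in seq_len(nrow(spec$effects))) {
        e <- spec$effects[r, ]
        col <- paste(e$network, e$side, e$measure, sep = "_")
        base_sd <- stats::sd(cohort[[col]])
        shifted <- cohort[[col]]
        shifted[high] <- shifted[high] + e$shift_sd * base_sd
        if (e$measure %in% c("count", "volume")) {
          shifted <- pmax(round(shifted), 0)
        } else {
          shifted <- pmax(shifted, 0)
        }
        cohort[[col]] <- shifted
      }
    }

    attr(cohort, "spec") <- spec
    class(cohort) <- c("pvs_cohort", class(cohort))
    cohort
  })
}

#' Write / read a cohort CSV
#'
#' One row per subject, one column per (network, side, measure); values
#' round-trip losslessly.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           sex = readr::col_character(),
                           language = readr::col_character(),
                           sensory = readr::col_character(),
                           stereotypies = readr::col_character(),
                           support_level = readr::col_integer(),
                           .default = readr::col_double()
                         ))
  class(out) <- c("pvs_cohort", class(out))
  out
}
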