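# Extreme-of-outcome group comparison: split a cohort on one symptom into
# its lowest- and highest-severity categories (intermediate and unknown are
# excluded), run Mann-Whitney U tests per (network, side, measure), and map
# the per-cell significance counts to a yellow/orange/red severity color.

#' Split a cohort by the extreme-of-outcome rule
#'
#' Partitions the cohort into the low- and high-severity groups of one
#' symptom; intermediate categories and unknown values are always excluded.
#' The packaged presets are: `language` (none/low vs absent language,
#' intermediate excluded), `sensory` (no vs yes, unknown excluded),
#' `stereotypies` (no vs yes, unknown excluded), `support_level` (level 1 vs
#' level 3, level 2 excluded).
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param symptom One of `"language"`, `"sensory"`, `"stereotypies"`,
#'   `"support_level"`.
#' @return A list of class `pvs_split` with tibbles `low`, `high`,
#'   `excluded` and the `symptom` name. An empty low or high group is an
#'   error (the comparison would be undefined).
#' @export
split_cohort <- function(cohort, symptom) {
  if (!is.character(symptom) || length(symptom) != 1 ||
      !symptom %in% .pvs_symptoms) {
    stop("`symptom` must be one of: ", paste(.pvs_symptoms, collapse = ", "),
         call. = FALSE)
  }
  preset <- .split_presets[[symptom]]
  if (!preset$field %in% names(cohort)) {
    stop("cohort has no `", preset$field, "` column", call. = FALSE)
  }
  field <- as.character(cohort[[preset$field]])
  low <- cohort[field == preset$low, ]
  high <- cohort[field == preset$high, ]
  excluded <- cohort[!(field %in% c(preset$low, preset$high)), ]
  if (nrow(low) == 0 || nrow(high) == 0) {
    stop("extreme-of-outcome split on `", symptom,
         "` leaves an empty group (low n=", nrow(low), ", high n=",
         nrow(high), ")", call. = FALSE)
  }
  structure(list(low = low, high = high, excluded = excluded,
                 symptom = symptom),
            class = "pvs_split")
}

#' @export
print.pvs_split <- function(x, ...) {
  cat("<pvs_split> symptom: ", x$symptom, " — low n=", nrow(x$low),
      ", high n=", nrow(x$high), ", excluded n=", nrow(x$excluded), "\n",
      sep = "")
  invisible(x)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank test of a location difference. The exact U distribution is
#' used when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with continuity and tie correction is
#' used. The reported U statistic is for the low group (first argument).
#'
#' @param low,high Numeric value vectors, each non-empty.
#' @return A tibble with `U`, `p_value`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(low, high) {
  if (length(low) < 1 || length(high) < 1) {
    stop("both groups need at least one observation", call. = FALSE)
  }
  combined <- c(low, high)
  tie_free <- !any(duplicated(combined))
  use_exact <- (length(combined) <= 20) && tie_free
  wt <- suppressWarnings(stats::wilcox.test(low, high, exact = use_exact,
                                            correct = TRUE))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (use_exact) "exact" else "normal_approx")
}

#' Run all network-level group comparisons
#'
#' Splits the cohort on one symptom (extreme-of-outcome) and runs one
#' Mann-Whitney U test per (network, side, measure): 3 networks x 2 sides x
#' 3 measures = 18 comparisons. No multiplicity correction is applied by
#' default (each cell is judged at `p < alpha`); `fdr = TRUE` adds
#' Benjamini-Hochberg adjusted p-values and bases the significance flag on
#' them instead.
#'
#' @param cohort Cohort tibble with `<network>_<side>_<measure>` columns.
#' @param symptom Symptom to split on; see [split_cohort()].
#' @param measures Subset of `c("count", "volume", "diameter")`.
#' @param alpha Significance level.
#' @param fdr Apply Benjamini-Hochberg correction across the comparisons.
#' @return A tibble of class `pvs_comparison`: `network`, `side`, `measure`,
#'   `U`, `p_value` (and `p_adj` with `fdr`), `significant`, `median_low`,
#'   `iqr_low`, `median_high`, `iqr_high`; attributes carry the symptom,
#'   group sizes and settings.
#' @export
run_comparisons <- function(cohort, symptom,
                            measures = c("count", "volume", "diameter"),
                            alpha = 0.05, fdr = FALSE) {
  measures <- match.arg(measures, .pvs_measures, several.ok = TRUE)
  sp <- split_cohort(cohort, symptom)
  grid <- tidyr::expand_grid(network = .pvs_networks, side = .pvs_sides,
                             measure = measures)
  rows <- purrr::pmap(grid, function(network, side, measure) {
    col <- paste(network, side, measure, sep = "_")
    if (!col %in% names(cohort)) {
      stop("cohort has no metric column `", col, "`", call. = FALSE)
    }
    lo <- sp$low[[col]]
    hi <- sp$high[[col]]
    mw <- mann_whitney(lo, hi)
    tibble::tibble(
      network = network, side = side, measure = measure,
      U = mw$U, p_value = mw$p_value,
      median_low = stats::median(lo), iqr_low = stats::IQR(lo),
      median_high = stats::median(hi), iqr_high = stats::IQR(hi)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (fdr) {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[, c("network", "side", "measure", "U", "p_value",
                 if (fdr) "p_adj", "significant",
                 "median_low", "iqr_low", "median_high", "iqr_high")]
  attr(out, "symptom") <- symptom
  attr(out, "n_low") <- nrow(sp$low)
  attr(out, "n_high") <- nrow(sp$high)
  attr(out, "n_excluded") <- nrow(sp$excluded)
  attr(out, "alpha") <- alpha
  attr(out, "fdr") <- fdr
  class(out) <- c("pvs_comparison", class(out))
  out
}

.severity_colors <- c("none", "yellow", "orange", "red")

#' Severity map from comparison results
#'
#' Per (network, side), counts how many of the three PVS measures (count,
#' volume, diameter) differ significantly between the groups and maps the
#' count to a color: 0 = none, 1 = yellow (single abnormality), 2 = orange
#' (two abnormalities), 3 = red (all three abnormalities).
#'
#' @param results A `pvs_comparison` tibble covering all 3 networks x
#'   2 sides x 3 measures; missing cells are an error.
#' @return A tibble of class `pvs_severity` with `network`, `side`,
#'   `n_significant`, `color`.
#' @export
severity_map <- function(results) {
  grid <- tidyr::expand_grid(network = .pvs_networks, side = .pvs_sides,
                             measure = .pvs_measures)
  have <- paste(results$network, results$side, results$measure)
  missing_cells <- setdiff(paste(grid$network, grid$side, grid$measure), have)
  if (length(missing_cells) > 0) {
    stop("severity_map needs all 18 (network, side, measure) cells; missing: ",
         paste(missing_cells, collapse = "; "), call. = FALSE)
  }
  out <- results |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$network, .data$side) |>
    dplyr::summarise(n_significant = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(color = .severity_colors[.data$n_significant + 1]) |>
    dplyr::arrange(match(.data$network, .pvs_networks),
                   match(.data$side, .pvs_sides))
  for (a in c("symptom", "n_low", "n_high", "n_excluded", "alpha")) {
    attr(out, a) <- attr(results, a, exact = TRUE)
  }
  class(out) <- c("pvs_severity", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_comparisons
#' @param x A `pvs_comparison` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.pvs_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pvs_comparison")
  tibble::as_tibble(out)
}

#' @rdname run_comparisons
#' @export
#' @exportS3Method generics::glance
glance.pvs_comparison <- function(x, ...) {
  tibble::tibble(
    symptom = attr(x, "symptom", exact = TRUE),
    n_low = attr(x, "n_low", exact = TRUE),
    n_high = attr(x, "n_high", exact = TRUE),
    n_excluded = attr(x, "n_excluded", exact = TRUE),
    alpha = attr(x, "alpha", exact = TRUE),
    fdr = attr(x, "fdr", exact = TRUE),
    n_comparisons = nrow(x),
    n_significant = sum(x$significant)
  )
}

#' Plot a severity map
#'
#' Tile panel of the six (network, side) cells tinted none/yellow/orange/red
#' by the number of significant PVS measures, analogous to the published
#' network maps.
#'
#' @param object,x A `pvs_severity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pvs_severity <- function(object, ...) {
  fills <- c(none = "grey85", yellow = "#F7D842", orange = "#F08C00",
             red = "#D7263D")
  symptom <- attr(object, "symptom", exact = TRUE)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$side, y = .data$network,
                               fill = .data$color)) +
    ggplot2::geom_tile(color = "white", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$n_significant, "/3"))) +
    ggplot2::scale_fill_manual(values = fills, drop = FALSE,
                               name = "abnormal measures") +
    ggplot2::labs(
      title = if (is.null(symptom)) "PVS severity map" else
        paste0("PVS severity map — ", symptom),
      x = "hemisphere", y = "network"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pvs_severity
#' @export
plot_severity_map <- function(x, ...) autoplot.pvs_severity(x, ...)
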