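#' Relative growth rate from two shoot dry weights
#'
#' RGR = (ln(SDW2) - ln(SDW1)) / dt, in grams of new growth per gram of
#' existing plant per day. SDW1 is the harvest weight at the end of drought
#' stress and SDW2 the harvest weight after re-watering; negative values mean
#' the plant lost mass. Zero or negative weights indicate data errors and are
#' rejected rather than clamped (the logarithm is undefined there).
#'
#' @param sdw1,sdw2 Shoot dry weights (g), strictly positive. Vectorized.
#' @param dt Days between the two harvests, strictly positive.
#' @return RGR in g g^-1 d^-1.
#' @export
#' @examples
#' compute_rgr(0.5, 2.0, 7) # log(4)/7
compute_rgr <- function(sdw1, sdw2, dt) {
  if (any(!is.finite(sdw1)) || any(sdw1 <= 0) ||
      any(!is.finite(sdw2)) || any(sdw2 <= 0)) {
    stop("shoot dry weights must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("dt must be finite and > 0", call. = FALSE)
  }
  (log(sdw2) - log(sdw1)) / dt
}

#' Per-plant growth rate over a measurement window
#'
#' Simple difference rate `(value_end - value_start) / dt` in trait units per
#' day. Negative rates are legitimate: destructive sampling measures
#' different plants at the two endpoints, so apparent shrinkage can occur.
#'
#' @param pairs Output of [select_window()].
#' @return The same tibble with a `rate` column appended.
#' @export
compute_trait_growth_rate <- function(pairs) {
  stopifnot(all(c("value_start", "value_end", "dt") %in% names(pairs)))
  dplyr::mutate(pairs, rate = (.data$value_end - .data$value_start) / .data$dt)
}

#' Aggregate per-plant rates to line-level growth-rate records
#'
#' Two-stage unweighted mean following the field design: plants are averaged
#' within plot, then plot means are averaged within genotype x treatment.
#' Plants and plots are weighted equally at their own level regardless of
#' how many plants a plot contributed.
#'
#' @param plant_rates A tibble with `genotype_id`, `treatment`, `plot_id`,
#'   `plant_id` and `rate` (as from [compute_trait_growth_rate()]).
#' @param compartment `"shoot"` or `"root"`; carried as a label.
#' @param window Character vector of the two window labels, e.g.
#'   `c("M2", "M3")`; carried as a label.
#' @return One record per genotype x treatment: `genotype_id`, `treatment`,
#'   `compartment`, `window_start`, `window_end`, `rate`, `n_plots`,
#'   `n_plants`.
#' @export
aggregate_rates <- function(plant_rates, compartment = c("shoot", "root"),
                            window = c(NA_character_, NA_character_)) {
  compartment <- match.arg(compartment)
  stopifnot(all(c("genotype_id", "treatment", "plot_id", "plant_id", "rate")
                %in% names(plant_rates)))
  if (nrow(plant_rates) == 0) {
    stop("no plant rates to aggregate", call. = FALSE)
  }
  plot_means <- plant_rates |>
    dplyr::group_by(.data$genotype_id, .data$treatment, .data$plot_id) |>
    dplyr::summarise(rate = mean(.data$rate), n_plants = dplyr::n(),
                     .groups = "drop")
  plot_means |>
    dplyr::group_by(.data$genotype_id, .data$treatment) |>
    dplyr::summarise(rate = mean(.data$rate), n_plots = dplyr::n(),
                     n_plants = sum(.data$n_plants), .groups = "drop") |>
    dplyr::mutate(compartment = compartment,
                  window_start = window[1], window_end = window[2]) |>
    dplyr::select("genotype_id", "treatment", "compartment",
                  "window_start", "window_end", "rate", "n_plots", "n_plants")
}

#' Block-centre values to remove additive spatial variation
#'
#' Subtracts each block's deviation from the grand mean. This removes purely
#' additive block effects exactly, leaves balanced designs unchanged, and
#' conserves the grand mean. It is a deliberately simple, reproducible
#' adjustment for augmented field designs in place of a mixed-model
#' least-squares-means fit; outputs are labelled "block-adjusted".
#'
#' @param values Numeric vector.
#' @param blocks Block label per value.
#' @return Numeric vector of block-centred values.
#' @export
block_center <- function(values, blocks) {
  stopifnot(length(values) == length(blocks), is.numeric(values))
  if (length(unique(blocks)) < 2) {
    message("single block: block-centring is the identity")
    return(values)
  }
  grand <- mean(values)
  block_dev <- tapply(values, blocks, mean) - grand
  values - block_dev[as.character(blocks)]
}

#' Block-adjusted genotype means of RGR
#'
#' Applies [block_center()] to per-plot RGR values and averages the adjusted
#' values per genotype (within treatment when a `treatment` column is
#' present).
#'
#' @param rgr_records A tibble with `genotype_id`, `block_id`, `rgr` and
#'   optionally `treatment`.
#' @return A tibble of block-adjusted genotype means (`rgr_adj`), with
#'   `n_blocks`.
#' @export
block_adjust_rgr <- function(rgr_records) {
  stopifnot(all(c("genotype_id", "block_id", "rgr") %in% names(rgr_records)))
  grp <- intersect("treatment", names(rgr_records))
  rgr_records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(rgr_adj = block_center(.data$rgr, .data$block_id)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("genotype_id", grp)))) |>
    dplyr::summarise(rgr_adj = mean(.data$rgr_adj),
                     n_blocks = dplyr::n_distinct(.data$block_id),
                     .groups = "drop")
}
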