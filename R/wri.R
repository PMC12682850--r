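#' Rescale a vector linearly onto [1, 100]
#'
#' Growth rates from destructive sampling can be negative, so before taking
#' log-ratios each (treatment, compartment) group of line means is mapped
#' affinely onto the interval \[1, 100\]: `x -> 1 + 99 * (x - min) / (max -
#' min)`. The map is order-preserving; a constant vector (max == min) maps to
#' the interval midpoint 50.5 so that downstream log-ratios stay defined.
#'
#' @param values Non-empty numeric vector, all finite.
#' @return Numeric vector in \[1, 100\].
#' @export
#' @examples
#' rescale_1_100(c(0, 5, 10)) # 1, 50.5, 100
rescale_1_100 <- function(values) {
  if (length(values) == 0) stop("cannot rescale an empty vector", call. = FALSE)
  if (any(!is.finite(values))) stop("values must all be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(50.5, length(values)))
  # clamp: floating-point round-off must not push endpoints past 1 or 100
  pmin(pmax(1 + 99 * (values - rng[1]) / (rng[2] - rng[1]), 1), 100)
}

#' Shoot-to-root growth-rate ratio (SRGR)
#'
#' Natural log of the rescaled shoot growth rate over the rescaled root
#' growth rate. The log restores symmetry between shoot- and root-dominated
#' lines and gives an approximately normal distribution across genotypes.
#' Zero means equal investment in both compartments.
#'
#' @param rescaled_shoot,rescaled_root Rescaled rates in \[1, 100\].
#'   Vectorized.
#' @return `log(rescaled_shoot / rescaled_root)`.
#' @export
compute_srgr <- function(rescaled_shoot, rescaled_root) {
  chk <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 1) || any(x > 100)) {
      stop(what, " must lie in [1, 100]", call. = FALSE)
    }
  }
  chk(rescaled_shoot, "rescaled_shoot")
  chk(rescaled_root, "rescaled_root")
  log(rescaled_shoot / rescaled_root)
}

#' Water Recovery Index
#'
#' WRI = SRGR(drought) - SRGR(well-watered). More negative values mean the
#' line shifts investment towards crown-root production (relative to shoot
#' growth) under drought recovery compared to its own well-watered
#' behaviour; values near zero mean little treatment contrast. The index is
#' a within-experiment ranking tool: it depends on plant age and growth
#' stage and is not comparable across experiments.
#'
#' @param srgr_drought,srgr_well_watered Finite SRGR values. Vectorized.
#' @return The WRI.
#' @export
compute_wri <- function(srgr_drought, srgr_well_watered) {
  if (any(!is.finite(srgr_drought)) || any(!is.finite(srgr_well_watered))) {
    stop("SRGR values must be finite", call. = FALSE)
  }
  srgr_drought - srgr_well_watered
}

#' Rank genotypes by WRI into recovery strategies
#'
#' Sorts ascending by WRI (rank 1 = most negative). Ties are broken by
#' lexicographic genotype id for determinism. The lower half of the ranking
#' is labelled `"conservative"` (strong root-biased regrowth after
#' re-watering), the upper half `"less_conservative"` (growth maintained
#' through drought with little treatment contrast).
#'
#' @param wri_records A tibble with `genotype_id` and `wri` (>= 2 rows).
#' @return The table sorted ascending by WRI with `strategy_rank` and
#'   `strategy` columns appended.
#' @export
rank_strategies <- function(wri_records) {
  stopifnot(all(c("genotype_id", "wri") %in% names(wri_records)))
  if (nrow(wri_records) < 2) {
    stop("need at least two genotypes to rank strategies", call. = FALSE)
  }
  out <- wri_records[order(wri_records$wri, wri_records$genotype_id), ]
  out$strategy_rank <- seq_len(nrow(out))
  out$strategy <- ifelse(out$strategy_rank <= nrow(out) / 2,
                         "conservative", "less_conservative")
  out
}

#' Water Recovery Index pipeline from a phenotype table
#'
#' Runs the full WRI computation: pairs shoot (total leaf length) and root
#' (crown root number) measurements over a window, computes per-plant rates,
#' averages plants within plot then plots within line, rescales line means
#' to \[1, 100\] separately per (treatment, compartment), forms SRGR per
#' treatment and the WRI as their drought-minus-control difference, and
#' ranks genotypes. Genotypes lacking a treatment are excluded with a
#' warning.
#'
#' @param obs A validated phenotype table.
#' @param schedule A schedule tibble from [measurement_schedule()].
#' @param window Window labels, default `c("M2", "M3")` (end of drought to
#'   early recovery — the window where the recovery contrast lives).
#' @param shoot_trait,root_trait Traits used as shoot and root growth
#'   proxies.
#' @return A tibble with `genotype_id`, `srgr_drought`, `srgr_well_watered`,
#'   `wri`, `strategy_rank`, `strategy`, sorted by rank. Attribute
#'   `line_rates` holds the intermediate line-level rate table.
#' @export
compute_wri_table <- function(obs, schedule, window = c("M2", "M3"),
                              shoot_trait = "leaf_length_total",
                              root_trait = "crown_root_count") {
  rates <- dplyr::bind_rows(
    aggregate_rates(
      compute_trait_growth_rate(
        select_window(obs, schedule, window[1], window[2], shoot_trait)),
      compartment = "shoot", window = window),
    aggregate_rates(
      compute_trait_growth_rate(
        select_window(obs, schedule, window[1], window[2], root_trait)),
      compartment = "root", window = window)
  )
  rates <- rates |>
    dplyr::group_by(.data$treatment, .data$compartment) |>
    dplyr::mutate(rescaled = rescale_1_100(.data$rate)) |>
    dplyr::ungroup()

  srgr <- rates |>
    dplyr::select("genotype_id", "treatment", "compartment", "rescaled") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "rescaled") |>
    dplyr::mutate(srgr = compute_srgr(.data$shoot, .data$root)) |>
    dplyr::select("genotype_id", "treatment", "srgr") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "srgr",
                       names_prefix = "srgr_")

  incomplete <- is.na(srgr$srgr_drought) | is.na(srgr$srgr_well_watered)
  if (any(incomplete)) {
    warning("excluding genotype(s) missing a treatment: ",
            paste(srgr$genotype_id[incomplete], collapse = ", "),
            call. = FALSE)
    srgr <- srgr[!incomplete, ]
  }
  out <- srgr |>
    dplyr::mutate(wri = compute_wri(.data$srgr_drought,
                                    .data$srgr_well_watered)) |>
    rank_strategies()
  attr(out, "line_rates") <- rates
  out
}
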