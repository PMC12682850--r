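#' Configuration for the synthetic recovery field experiment
#'
#' Emulates the field design used to derive the Water Recovery Index:
#' 20 genotypes x 2 treatments (drought / well-watered) x 4 replicate plots
#' x 2 marked plants, measured at four timepoints, with control sampling of
#' M2/M3 delayed by one day relative to the drought plots. Each genotype
#' carries a latent `strategy` in \[0, 1\]: 0 = conservative (shoot growth
#' strongly suppressed by drought, strong crown-root boost after
#' re-watering), 1 = less-conservative (growth maintained through drought,
#' little treatment contrast). A per-genotype `vigor` multiplier models
#' genetic size variation and applies to both compartments and treatments,
#' so it cancels in the WRI contrast.
#'
#' Effect sizes are multiplicative factors on the underlying growth rates,
#' linearly interpolated from their strategy-0 value to 1 (no effect) at
#' strategy 1. Noise is multiplicative lognormal at plot and plant level
#' (keeping traits positive), expressed as coefficients of variation.
#'
#' @param n_genotypes,n_plots,n_plants Design counts.
#' @param schedule Measurement schedule (defaults to the drought
#'   29/34/37/42, control 29/35/38/42 DAS calendar).
#' @param strategy Per-genotype strategy values in \[0, 1\]; default evenly
#'   spaced.
#' @param shoot_suppression Drought multiplier on the shoot rate at
#'   strategy 0 (before and shortly after re-watering), default 0.5.
#' @param root_boost Post-re-watering multiplier on the crown-root rate at
#'   strategy 0, default 1.5.
#' @param drought_root_suppression Drought multiplier on the crown-root
#'   rate before re-watering (all strategies), default 0.5.
#' @param base_shoot_rate,base_root_rate Well-watered rates: cm of leaf
#'   length per day, crown roots per day.
#' @param base_leaf_length,base_crown_roots Trait values at M1 for a plant
#'   of vigor 1.
#' @param vigor_cv,plot_cv,plant_cv Lognormal coefficients of variation for
#'   genotype vigor, plot-level and plant-level rate noise.
#' @param seed Default seed used by [gen_field_phenotypes()].
#' @return A `field_sim_config` list.
#' @export
field_sim_config <- function(n_genotypes = 20, n_plots = 4, n_plants = 2,
                             schedule = measurement_schedule(
                               drought = c(M1 = 29, M2 = 34, M3 = 37, M4 = 42),
                               well_watered = c(M1 = 29, M2 = 35, M3 = 38, M4 = 42)),
                             strategy = seq(0, 1, length.out = n_genotypes),
                             shoot_suppression = 0.5, root_boost = 1.5,
                             drought_root_suppression = 0.5,
                             base_shoot_rate = 2, base_root_rate = 2,
                             base_leaf_length = 30, base_crown_roots = 8,
                             vigor_cv = 0.2, plot_cv = 0.10, plant_cv = 0.15,
                             seed = 1L) {
  stopifnot(n_genotypes >= 1, n_plots >= 1, n_plants >= 1,
            length(strategy) == n_genotypes,
            all(strategy >= 0 & strategy <= 1),
            shoot_suppression > 0, root_boost > 0,
            drought_root_suppression > 0,
            vigor_cv >= 0, plot_cv >= 0, plant_cv >= 0)
  structure(list(
    n_genotypes = n_genotypes, n_plots = n_plots, n_plants = n_plants,
    schedule = schedule, strategy = strategy,
    shoot_suppression = shoot_suppression, root_boost = root_boost,
    drought_root_suppression = drought_root_suppression,
    base_shoot_rate = base_shoot_rate, base_root_rate = base_root_rate,
    base_leaf_length = base_leaf_length, base_crown_roots = base_crown_roots,
    vigor_cv = vigor_cv, plot_cv = plot_cv, plant_cv = plant_cv,
    seed = as.integer(seed)), class = "field_sim_config")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.lnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# linear interpolation of an effect factor from `at0` (strategy 0) to 1
.interp_effect <- function(at0, strategy) at0 + (1 - at0) * strategy

#' Generate a synthetic recovery field phenotype table
#'
#' Leaf length grows linearly between timepoints; crown-root counts grow
#' piecewise (suppressed under drought before re-watering, boosted after
#' re-watering with the boost strongest for conservative genotypes). Rates
#' carry multiplicative lognormal noise shared within plot plus independent
#' plant noise. Crown-root counts are rounded to integers at emission. The
#' generator is a pure function of (config, seed): the same seed reproduces
#' the table bitwise.
#'
#' @param config A [field_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list: `observations` (validated phenotype tibble; 2560 rows
#'   under the defaults) and `truth` (per-genotype strategy, vigor and true
#'   recovery-window rates per treatment).
#' @export
gen_field_phenotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "field_sim_config"))
  withr::with_seed(seed, {
    genotypes <- sprintf("G%02d", seq_len(config$n_genotypes))
    geno <- tibble::tibble(
      genotype_id = genotypes,
      strategy = config$strategy,
      vigor = .lnorm_mult(config$n_genotypes, config$vigor_cv))

    plants <- tidyr::expand_grid(
      genotype_id = genotypes,
      treatment = TREATMENTS,
      plot = seq_len(config$n_plots),
      plant = seq_len(config$n_plants)) |>
      dplyr::mutate(block_id = sprintf("B%d", .data$plot),
                    plot_id = sprintf("%s_B%d", substr(.data$treatment, 1, 1),
                                      .data$plot),
                    plant_id = sprintf("P%d", .data$plant))

    windows <- tibble::tibble(window = 1:3)
    cells <- tidyr::expand_grid(plants, windows,
                                compartment = c("shoot", "root")) |>
      dplyr::left_join(geno, by = "genotype_id")

    base <- ifelse(cells$compartment == "shoot",
                   config$base_shoot_rate, config$base_root_rate)
    drought <- cells$treatment == "drought"
    fac <- rep(1, nrow(cells))
    sh <- cells$compartment == "shoot"
    # drought phase (M1->M2) and early recovery (M2->M3): shoot suppressed
    fac[drought & sh & cells$window <= 2] <-
      .interp_effect(config$shoot_suppression,
                     cells$strategy[drought & sh & cells$window <= 2])
    # drought phase: crown-root production suppressed for everyone
    fac[drought & !sh & cells$window == 1] <- config$drought_root_suppression
    # early recovery: crown-root boost, strongest for conservative lines
    fac[drought & !sh & cells$window == 2] <-
      .interp_effect(config$root_boost,
                     cells$strategy[drought & !sh & cells$window == 2])
    cells$true_rate <- base * cells$vigor * fac

    # plot and plant effects are whole-plant growth multipliers (soil patch,
    # individual plant vigour): shared across compartments within a window,
    # redrawn per window (environmental fluctuation over time)
    plot_noise <- cells |>
      dplyr::distinct(.data$genotype_id, .data$treatment, .data$plot,
                      .data$window) |>
      dplyr::mutate(plot_mult = .lnorm_mult(dplyr::n(), config$plot_cv))
    plant_noise <- cells |>
      dplyr::distinct(.data$genotype_id, .data$treatment, .data$plot,
                      .data$plant, .data$window) |>
      dplyr::mutate(plant_mult = .lnorm_mult(dplyr::n(), config$plant_cv))
    cells <- cells |>
      dplyr::left_join(plot_noise,
                       by = c("genotype_id", "treatment", "plot", "window")) |>
      dplyr::left_join(plant_noise,
                       by = c("genotype_id", "treatment", "plot", "plant",
                              "window")) |>
      dplyr::mutate(rate = .data$true_rate * .data$plot_mult * .data$plant_mult)

    # integrate rates into trait trajectories over the treatment's calendar
    sched <- config$schedule |>
      dplyr::mutate(tp = match(.data$label, TIMEPOINTS))
    dt_tbl <- sched |>
      dplyr::group_by(.data$treatment) |>
      dplyr::arrange(.data$tp, .by_group = TRUE) |>
      dplyr::mutate(window = .data$tp - 1L, dt = .data$das - dplyr::lag(.data$das)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$window >= 1) |>
      dplyr::select("treatment", "window", "dt")

    deltas <- cells |>
      dplyr::inner_join(dt_tbl, by = c("treatment", "window")) |>
      dplyr::mutate(delta = .data$rate * .data$dt)

    traj <- deltas |>
      dplyr::arrange(.data$window) |>
      dplyr::reframe(tp = c(1L, .data$window + 1L),
                     value_raw = cumsum(c(0, .data$delta)),
                     vigor = .data$vigor[1],
                     .by = c("genotype_id", "treatment", "block_id",
                             "plot_id", "plant_id", "compartment"))

    obs <- traj |>
      dplyr::mutate(
        trait = ifelse(.data$compartment == "shoot",
                       "leaf_length_total", "crown_root_count"),
        start = ifelse(.data$compartment == "shoot",
                       config$base_leaf_length, config$base_crown_roots),
        value = .data$start * .data$vigor + .data$value_raw,
        value = ifelse(.data$trait == "crown_root_count",
                       round(pmax(.data$value, 0)), pmax(.data$value, 0)),
        label = TIMEPOINTS[.data$tp]) |>
      dplyr::inner_join(sched, by = c("treatment", "label", "tp")) |>
      dplyr::select("genotype_id", "treatment", "block_id", "plot_id",
                    "plant_id", "das", "trait", "value") |>
      dplyr::arrange(.data$genotype_id, .data$treatment, .data$plot_id,
                     .data$plant_id, .data$trait, .data$das)

    truth <- geno |>
      dplyr::mutate(
        shoot_rate_ww = config$base_shoot_rate * .data$vigor,
        root_rate_ww = config$base_root_rate * .data$vigor,
        shoot_rate_drought_recovery = config$base_shoot_rate * .data$vigor *
          .interp_effect(config$shoot_suppression, .data$strategy),
        root_rate_drought_recovery = config$base_root_rate * .data$vigor *
          .interp_effect(config$root_boost, .data$strategy))

    list(observations = validate_pheno(obs), truth = truth)
  })
}

#' Configuration for synthetic multi-season GWAS summary tables
#'
#' Emulates per-season association scans over several field seasons:
#' background SNPs with uniform p-values plus planted peaks shared across
#' seasons whose positions jitter by at most a quarter of the co-location
#' window (so planted clusters are always linkable at the stated window).
#'
#' @param seasons Season labels, default three consecutive years.
#' @param chromosomes Chromosome names.
#' @param chrom_length_bp Chromosome length for background positions.
#' @param n_snps_per_chrom Background SNPs per chromosome per season.
#' @param peaks A tibble with `chrom`, `pos`, `seasons` (comma-separated
#'   subset of `seasons`) and `neglog10p` per planted peak.
#' @param window_bp Co-location window the jitter is calibrated to.
#' @param background_max_neglog10p Optional cap on background -log10(p)
#'   (e.g. 3 to keep background strictly below the co-location filter);
#'   `NULL` leaves p ~ Uniform(0, 1).
#' @param maf_range Range for simulated minor allele frequencies.
#' @param check_separation Assert planted peaks on a chromosome are
#'   separated by more than `2 * window_bp` (required when recovery of
#'   exactly k clusters is asserted).
#' @param seed Default seed used by [gen_gwas_tables()].
#' @return A `gwas_sim_config` list.
#' @export
gwas_sim_config <- function(seasons = c("2017", "2018", "2019"),
                            chromosomes = c("1", "2"),
                            chrom_length_bp = 30e6,
                            n_snps_per_chrom = 1000,
                            peaks = tibble::tibble(
                              chrom = character(), pos = numeric(),
                              seasons = character(), neglog10p = numeric()),
                            window_bp = 100000,
                            background_max_neglog10p = NULL,
                            maf_range = c(0.05, 0.5),
                            check_separation = TRUE,
                            seed = 1L) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(length(seasons) >= 2, chrom_length_bp > 0, n_snps_per_chrom >= 0,
            window_bp > 0)
  if (check_separation && nrow(peaks) > 1) {
    for (ch in unique(peaks$chrom)) {
      p <- sort(peaks$pos[peaks$chrom == ch])
      if (length(p) > 1 && any(diff(p) <= 2 * window_bp)) {
        stop("planted peaks on chromosome ", ch,
             " must be separated by more than 2 * window_bp", call. = FALSE)
      }
    }
  }
  structure(list(
    seasons = as.character(seasons), chromosomes = as.character(chromosomes),
    chrom_length_bp = chrom_length_bp, n_snps_per_chrom = n_snps_per_chrom,
    peaks = peaks, window_bp = window_bp,
    background_max_neglog10p = background_max_neglog10p,
    maf_range = maf_range, seed = as.integer(seed)),
    class = "gwas_sim_config")
}

#' Generate synthetic per-season GWAS summary tables
#'
#' @param config A [gwas_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list: `hits` (validated hit tibble over all seasons) and
#'   `truth` (planted peak id, chromosome, nominal position and the realized
#'   jittered interval).
#' @export
gen_gwas_tables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "gwas_sim_config"))
  withr::with_seed(seed, {
    p_max <- 1
    p_min <- if (is.null(config$background_max_neglog10p)) 0 else
      10^(-config$background_max_neglog10p)
    grid <- tidyr::expand_grid(season = config$seasons,
                               chrom = config$chromosomes)
    n_bg <- config$n_snps_per_chrom * nrow(grid)
    background <- tibble::tibble(
      season = rep(grid$season, each = config$n_snps_per_chrom),
      chrom = rep(grid$chrom, each = config$n_snps_per_chrom),
      pos = ceiling(runif(n_bg, 0, config$chrom_length_bp)),
      pvalue = runif(n_bg, p_min, p_max),
      maf = runif(n_bg, config$maf_range[1], config$maf_range[2]))
    background$snp_id <- sprintf("bg_%s_c%s_%06d", background$season,
                                 background$chrom, seq_len(nrow(background)))

    planted <- NULL
    truth <- tibble::tibble(peak_id = character(), chrom = character(),
                            pos = numeric(), seasons = character(),
                            start = numeric(), end = numeric())
    if (nrow(config$peaks) > 0) {
      rows <- lapply(seq_len(nrow(config$peaks)), function(i) {
        pk <- config$peaks[i, ]
        seas <- strsplit(pk$seasons, ",")[[1]]
        stopifnot(all(seas %in% config$seasons), length(seas) >= 2)
        jit <- round(runif(length(seas), -config$window_bp / 4,
                           config$window_bp / 4))
        tibble::tibble(
          peak_id = sprintf("peak_%02d", i), season = seas,
          snp_id = sprintf("peak_%02d_%s", i, seas), chrom = pk$chrom,
          pos = pmax(1, pk$pos + jit),
          pvalue = 10^(-(pk$neglog10p + runif(length(seas), 0, 0.5))),
          maf = runif(length(seas), config$maf_range[1], config$maf_range[2]),
          nominal_pos = pk$pos)
      })
      planted <- dplyr::bind_rows(rows)
      truth <- planted |>
        dplyr::group_by(.data$peak_id, .data$chrom) |>
        dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                         pos = .data$nominal_pos[1],
                         seasons = paste(sort(.data$season), collapse = ","),
                         .groups = "drop") |>
        dplyr::select("peak_id", "chrom", "pos", "seasons", "start", "end")
    }
    hits <- dplyr::bind_rows(
      background[, c("season", "snp_id", "chrom", "pos", "pvalue", "maf")],
      if (!is.null(planted))
        planted[, c("season", "snp_id", "chrom", "pos", "pvalue", "maf")])
    list(hits = validate_gwas_hits(hits), truth = truth)
  })
}

#' Configuration for synthetic glasshouse root systems
#'
#' Emulates scanned rice root systems: a forest of axial roots (seminal and
#' crown), each bearing unbranched S-type laterals and branch-capable
#' L-type laterals which in turn bear second-order S-type laterals.
#' Diameters are drawn strictly inside their class bands; lengths are
#' lognormal. Drought multiplies the S-lateral count down and the L-lateral
#' count up; the recovered condition restores well-watered parameters
#' (root-system plasticity is reversible).
#'
#' @param n_axial Number of axial roots.
#' @param s_per_axial First-order S-type laterals per axial root
#'   (well-watered).
#' @param l_per_axial L-type laterals per axial root (well-watered).
#' @param s2_per_l Second-order S-type laterals per L-type lateral.
#' @param s_length_meanlog,s_length_sdlog Lognormal S-lateral length (mm).
#' @param l_length_meanlog,l_length_sdlog Lognormal L-lateral length (mm).
#' @param axial_length_meanlog,axial_length_sdlog Lognormal axial length (mm).
#' @param s_diameter_range,l_diameter_range,axial_diameter_range Uniform
#'   diameter bands (mm), strictly inside the S (<= 0.15), L ((0.15, 0.37\])
#'   and axial (> 0.37) classes.
#' @param drought_s_multiplier,drought_l_multiplier Count multipliers under
#'   drought.
#' @param seed Default seed used by [gen_root_system()].
#' @return A `root_sim_config` list.
#' @export
root_sim_config <- function(n_axial = 5, s_per_axial = 32, l_per_axial = 4,
                            s2_per_l = 2,
                            s_length_meanlog = log(7), s_length_sdlog = 0.2,
                            l_length_meanlog = log(40), l_length_sdlog = 0.3,
                            axial_length_meanlog = log(150),
                            axial_length_sdlog = 0.2,
                            s_diameter_range = c(0.05, 0.14),
                            l_diameter_range = c(0.16, 0.36),
                            axial_diameter_range = c(0.40, 0.80),
                            drought_s_multiplier = 0.5,
                            drought_l_multiplier = 1.5,
                            seed = 1L) {
  stopifnot(n_axial >= 1, s_per_axial >= 0, l_per_axial >= 0, s2_per_l >= 0,
            drought_s_multiplier > 0, drought_l_multiplier > 0,
            s_diameter_range[2] <= 0.15, l_diameter_range[1] > 0.15,
            l_diameter_range[2] <= 0.37, axial_diameter_range[1] > 0.37)
  structure(as.list(environment()), class = "root_sim_config")
}

#' Generate a synthetic root system
#'
#' @param config A [root_sim_config()].
#' @param condition `"well_watered"`, `"drought"` (fewer S, more L
#'   laterals) or `"recovered"` (identical to well-watered — the
#'   drought-adapted architecture is reversed after re-watering).
#' @param plant_id Plant identifier for the segment table.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list: `segments` (validated segment tibble) and `truth`
#'   (realized per-class totals, realized and distribution mean S-lateral
#'   length, lateral counts).
#' @export
gen_root_system <- function(config,
                            condition = c("well_watered", "drought", "recovered"),
                            plant_id = "plant_1", seed = config$seed) {
  stopifnot(inherits(config, "root_sim_config"))
  condition <- match.arg(condition)
  eff <- if (condition == "drought") {
    list(s = config$drought_s_multiplier, l = config$drought_l_multiplier)
  } else {
    list(s = 1, l = 1)  # recovered == well-watered parameters
  }
  n_s1 <- round(config$s_per_axial * eff$s)
  n_l <- round(config$l_per_axial * eff$l)
  n_s2 <- round(config$s2_per_l * eff$s)

  withr::with_seed(seed, {
    rows <- list()
    for (a in seq_len(config$n_axial)) {
      aid <- sprintf("A%02d", a)
      rows[[length(rows) + 1]] <- tibble::tibble(
        segment_id = aid, parent_segment_id = NA_character_,
        length = rlnorm(1, config$axial_length_meanlog,
                        config$axial_length_sdlog),
        diameter = runif(1, config$axial_diameter_range[1],
                         config$axial_diameter_range[2]))
      if (n_s1 > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          segment_id = sprintf("%s_S%03d", aid, seq_len(n_s1)),
          parent_segment_id = aid,
          length = rlnorm(n_s1, config$s_length_meanlog, config$s_length_sdlog),
          diameter = runif(n_s1, config$s_diameter_range[1],
                           config$s_diameter_range[2]))
      }
      for (l in seq_len(n_l)) {
        lid <- sprintf("%s_L%02d", aid, l)
        rows[[length(rows) + 1]] <- tibble::tibble(
          segment_id = lid, parent_segment_id = aid,
          length = rlnorm(1, config$l_length_meanlog, config$l_length_sdlog),
          diameter = runif(1, config$l_diameter_range[1],
                           config$l_diameter_range[2]))
        if (n_s2 > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            segment_id = sprintf("%s_S%03d", lid, seq_len(n_s2)),
            parent_segment_id = lid,
            length = rlnorm(n_s2, config$s_length_meanlog,
                            config$s_length_sdlog),
            diameter = runif(n_s2, config$s_diameter_range[1],
                             config$s_diameter_range[2]))
        }
      }
    }
    segments <- dplyr::bind_rows(rows)
    segments <- tibble::tibble(plant_id = plant_id, segments)
    cls <- classify_segment(segments$diameter)
    s_len <- segments$length[cls == "S_type"]
    truth <- list(
      condition = condition,
      class_totals = tibble::tibble(
        class = c("S_type", "L_type", "axial"),
        length = c(sum(segments$length[cls == "S_type"]),
                   sum(segments$length[cls == "L_type"]),
                   sum(segments$length[cls == "axial"]))),
      n_s_laterals = length(s_len),
      mean_s_length_realized = mean(s_len),
      mean_s_length_true = exp(config$s_length_meanlog +
                                 config$s_length_sdlog^2 / 2),
      n_s1_per_axial = n_s1, n_l_per_axial = n_l, n_s2_per_l = n_s2)
    list(segments = validate_segments(segments), truth = truth)
  })
}

#' Gravimetric watering target from water-holding capacity
#'
#' Glasshouse pots are watered to a fraction of the soil's maximum
#' water-holding capacity (WHC); the target gravimetric water content is
#' simply `fraction * max_whc_pct`, in % water by weight. For the sandy
#' loam used in such experiments (maximum WHC 22.3 % w/w), 75 % WHC is
#' 16.725 % w/w.
#'
#' @param max_whc_pct Maximum water-holding capacity, % w/w, > 0.
#' @param fraction Target fraction of WHC, in (0, 1].
#' @return Target gravimetric water content, % w/w.
#' @export
#' @examples
#' glasshouse_watering_target(22.3, 0.75) # 16.725
glasshouse_watering_target <- function(max_whc_pct, fraction) {
  if (!is.finite(max_whc_pct) || max_whc_pct <= 0) {
    stop("max_whc_pct must be > 0", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  fraction * max_whc_pct
}
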