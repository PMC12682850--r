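#' Run the drought-recovery analysis pipeline on synthetic data
#'
#' Orchestrates the full analysis: simulate the recovery field experiment,
#' compute growth rates and the WRI ranking, and optionally the GWAS
#' co-location and root-architecture stages plus the treatment-comparison
#' statistics. All outputs are plain CSVs plus a run log and a short text
#' summary; a rerun with the same configuration and seed reproduces the
#' CSVs byte for byte. Any stage failure aborts with the stage name.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param field_config A [field_sim_config()].
#' @param window WRI window labels, default `c("M2", "M3")`.
#' @param gwas_config Optional [gwas_sim_config()]; enables the co-location
#'   stage.
#' @param root_config Optional [root_sim_config()]; enables the
#'   root-architecture stage (well-watered, drought and recovered systems).
#' @param run_stats Run one-sample t-tests on centred line rates and the
#'   two-way genotype x treatment ANOVA on plant rates.
#' @return Invisibly, a list of the main result tables.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         field_config = field_sim_config(),
                         window = c("M2", "M3"),
                         gwas_config = NULL, root_config = NULL,
                         run_stats = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("rootshift pipeline run",
                 paste0("seed: ", seed),
                 paste0("wri window: ", paste(window, collapse = " -> ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate_field", gen_field_phenotypes(field_config, seed = seed))
  write_pheno_table(sim$observations, file.path(out_dir, "phenotypes.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "truth_field.csv"),
                   progress = FALSE)

  wri <- stage("wri", compute_wri_table(sim$observations,
                                        field_config$schedule,
                                        window = window))
  line_rates <- attr(wri, "line_rates")
  readr::write_csv(line_rates, file.path(out_dir, "line_rates.csv"),
                   progress = FALSE)
  readr::write_csv(wri, file.path(out_dir, "wri.csv"), progress = FALSE)
  log_lines <- c(log_lines,
                 paste0("genotypes ranked: ", nrow(wri)),
                 paste0("conservative extreme: ", wri$genotype_id[1]),
                 paste0("less-conservative extreme: ",
                        wri$genotype_id[nrow(wri)]))

  results <- list(wri = wri, line_rates = line_rates, truth = sim$truth)

  if (!is.null(gwas_config)) {
    gw <- stage("simulate_gwas", gen_gwas_tables(gwas_config, seed = seed))
    filtered <- stage("coloc_filter", filter_hits(gw$hits))
    clusters <- stage("coloc", find_colocations(filtered,
                                                gwas_config$window_bp))
    readr::write_csv(gw$hits, file.path(out_dir, "gwas_hits.csv"),
                     progress = FALSE)
    readr::write_csv(gw$truth, file.path(out_dir, "truth_gwas.csv"),
                     progress = FALSE)
    readr::write_csv(clusters[setdiff(names(clusters), "members")],
                     file.path(out_dir, "coloc_clusters.csv"),
                     progress = FALSE)
    dropped <- attr(filtered, "n_removed")
    log_lines <- c(log_lines,
                   paste0("gwas hits below -log10 p filter: ", dropped$pvalue),
                   paste0("gwas hits below MAF filter: ", dropped$maf),
                   paste0("co-location clusters: ", nrow(clusters)))
    results$coloc <- clusters
  }

  if (!is.null(root_config)) {
    conditions <- c("well_watered", "drought", "recovered")
    systems <- stage("simulate_roots", lapply(setNames(conditions, conditions),
      function(cond) gen_root_system(root_config, condition = cond,
                                     plant_id = cond, seed = seed)))
    segs <- dplyr::bind_rows(lapply(systems, `[[`, "segments"))
    summary_tbl <- stage("root_types", summarize_root_types(segs))
    links <- stage("link_analysis", link_analysis(segs))
    readr::write_csv(segs, file.path(out_dir, "root_segments.csv"),
                     progress = FALSE)
    readr::write_csv(summary_tbl, file.path(out_dir, "root_type_summary.csv"),
                     progress = FALSE)
    readr::write_csv(links, file.path(out_dir, "link_analysis.csv"),
                     progress = FALSE)
    results$root_types <- summary_tbl
    results$link_analysis <- links
  }

  if (run_stats) {
    # centre rates across treatments within a compartment, then test each
    # treatment's deviation from the pooled mean against zero
    tests <- stage("stats", {
      line_rates |>
        dplyr::group_by(.data$compartment) |>
        dplyr::mutate(rate_centered = center_to_zero_mean(.data$rate)) |>
        dplyr::group_by(.data$treatment, .data$compartment) |>
        dplyr::group_modify(~ one_sample_t(.x$rate_centered)) |>
        dplyr::ungroup()
    })
    readr::write_csv(tests, file.path(out_dir, "stats_one_sample_t.csv"),
                     progress = FALSE)
    results$stats <- tests
  }

  dropped_plants <- attr(line_rates, "n_dropped")
  log_lines <- c(log_lines,
                 paste0("window dropouts: ",
                        if (is.null(dropped_plants)) 0 else dropped_plants))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  writeLines(c(
    "Water Recovery Index summary",
    sprintf("%d genotypes ranked from conservative (most negative WRI)", nrow(wri)),
    sprintf("WRI range: %.4f to %.4f", min(wri$wri), max(wri$wri)),
    sprintf("most conservative: %s; least: %s",
            wri$genotype_id[1], wri$genotype_id[nrow(wri)])),
    file.path(out_dir, "summary.txt"))
  invisible(results)
}
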