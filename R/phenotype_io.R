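#' Validate a phenotype observation table
#'
#' A phenotype table holds one measured trait value per plant (or plot) per
#' day-after-sowing (DAS). Missing values are absent rows, never sentinel
#' numbers. Validation enforces the trait vocabulary, non-negative
#' measurements, integer crown-root counts and uniqueness of the
#' (genotype, treatment, plot, plant, das, trait) key.
#'
#' @param obs A data frame with columns `genotype_id`, `treatment`,
#'   `block_id`, `plot_id`, `plant_id`, `das`, `trait`, `value`.
#' @return The validated table as a tibble, invisibly usable downstream.
#' @export
validate_pheno <- function(obs) {
  required <- c("genotype_id", "treatment", "block_id", "plot_id",
                "plant_id", "das", "trait", "value")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::as_tibble(obs)[required]

  bad_treat <- setdiff(unique(obs$treatment), TREATMENTS)
  if (length(bad_treat) > 0) {
    stop("unknown treatment(s): ", paste(bad_treat, collapse = ", "),
         "; expected one of: ", paste(TREATMENTS, collapse = ", "),
         call. = FALSE)
  }
  bad_trait <- setdiff(unique(obs$trait), TRAITS)
  if (length(bad_trait) > 0) {
    stop("unknown trait(s): ", paste(bad_trait, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(obs$das) || anyNA(obs$das) ||
      any(obs$das < 0) || any(obs$das != round(obs$das))) {
    bad <- which(!is.finite(obs$das) | obs$das < 0 | obs$das != round(obs$das))
    stop("das must be a non-negative integer; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(obs$value) || anyNA(obs$value) || any(!is.finite(obs$value))) {
    bad <- which(!is.finite(obs$value))
    stop("value must be finite and numeric; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(obs$value < 0)
  if (length(neg) > 0) {
    stop("trait values must be >= 0; offending row(s): ",
         paste(head(neg, 5), collapse = ", "), call. = FALSE)
  }
  crc <- obs$trait == "crown_root_count"
  bad_crc <- which(crc & obs$value != round(obs$value))
  if (length(bad_crc) > 0) {
    stop("crown_root_count must be a non-negative integer; offending row(s): ",
         paste(head(bad_crc, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(obs$genotype_id, obs$treatment, obs$plot_id, obs$plant_id,
               obs$das, obs$trait, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (genotype, treatment, plot, plant, das, trait) key; ",
         "offending row(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  obs
}

#' Read a phenotype CSV
#'
#' Expects the long-format phenotype layout: one row per trait measurement,
#' columns `genotype_id,treatment,block_id,plot_id,plant_id,das,trait,value`,
#' UTF-8 with a mandatory header. Every row is validated; malformed numeric
#' fields are reported with their file line number (header = line 1).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of observations, row order preserved.
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("genotype_id", "treatment", "block_id", "plot_id",
                "plant_id", "das", "trait", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenotype CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " at file line(s): ",
           paste(head(bad + 1L, 5), collapse = ", "), call. = FALSE)
    }
    out
  }
  raw$das <- parse_num(raw$das, "das")
  raw$value <- parse_num(raw$value, "value")
  validate_pheno(raw)
}

#' Write a phenotype CSV
#'
#' Writes the fixed column order used by [read_pheno_table()]; numeric fields
#' keep full double precision so that write-then-read is the identity on
#' validated tables.
#'
#' @param obs A validated observation table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(obs, path) {
  obs <- validate_pheno(obs)
  readr::write_csv(obs, path, progress = FALSE)
  invisible(path)
}

#' Construct a measurement schedule
#'
#' Maps the destructive measurement labels M1--M4 to days-after-sowing,
#' separately per treatment: field logistics can shift control sampling by a
#' day relative to drought sampling, and elapsed time must always come from
#' the treatment's own calendar.
#'
#' @param drought,well_watered Named integer vectors, e.g.
#'   `c(M1 = 29, M2 = 34, M3 = 37, M4 = 42)`. Labels must be a subset of
#'   M1--M4 and DAS must strictly increase with the label order.
#' @return A tibble with columns `treatment`, `label`, `das`.
#' @export
#' @examples
#' measurement_schedule(
#'   drought      = c(M1 = 29, M2 = 34, M3 = 37, M4 = 42),
#'   well_watered = c(M1 = 29, M2 = 35, M3 = 38, M4 = 42)
#' )
measurement_schedule <- function(drought, well_watered) {
  one <- function(x, treatment) {
    labels <- names(x)
    if (is.null(labels) || !all(labels %in% TIMEPOINTS)) {
      stop("schedule labels must be among ", paste(TIMEPOINTS, collapse = ", "),
           call. = FALSE)
    }
    x <- x[order(match(labels, TIMEPOINTS))]
    if (any(diff(x) <= 0)) {
      stop("schedule DAS must strictly increase M1 < M2 < M3 < M4 (",
           treatment, ")", call. = FALSE)
    }
    tibble::tibble(treatment = treatment, label = names(x), das = as.integer(x))
  }
  dplyr::bind_rows(one(drought, "drought"), one(well_watered, "well_watered"))
}

#' Read a measurement schedule file
#'
#' Plain-text key-value format, one entry per line:
#' `<treatment> <label> <das>` (whitespace-separated; `#` comments and blank
#' lines ignored), e.g. `drought M2 34`.
#'
#' @param path Path to the schedule file.
#' @return A schedule tibble as from [measurement_schedule()].
#' @export
read_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    stop("malformed schedule line(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  entries <- split(setNames(as.integer(mat[, 3]), mat[, 2]), mat[, 1])
  missing_tr <- setdiff(TREATMENTS, names(entries))
  if (length(missing_tr) > 0) {
    stop("schedule file lacks treatment(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  measurement_schedule(drought = entries[["drought"]],
                       well_watered = entries[["well_watered"]])
}

#' Pair trait values at two schedule labels
#'
#' For every (genotype, treatment, plot, plant), extracts the trait value at
#' the start and end labels of a measurement window together with the elapsed
#' days computed from that treatment's own schedule. Plants missing either
#' endpoint are dropped and counted (attribute `n_dropped`); no value is ever
#' fabricated.
#'
#' @param obs A validated phenotype table.
#' @param schedule A schedule tibble from [measurement_schedule()].
#' @param start_label,end_label Window endpoints, e.g. `"M2"`, `"M3"`.
#' @param trait One trait name.
#' @return A tibble with columns `genotype_id`, `treatment`, `block_id`,
#'   `plot_id`, `plant_id`, `value_start`, `value_end`, `dt`; attribute
#'   `n_dropped` counts plants lacking an endpoint.
#' @export
select_window <- function(obs, schedule, start_label, end_label, trait) {
  obs <- validate_pheno(obs)
  stopifnot(trait %in% TRAITS)
  ends <- schedule[schedule$label %in% c(start_label, end_label), ]
  for (tr in unique(obs$treatment)) {
    have <- ends$label[ends$treatment == tr]
    if (!all(c(start_label, end_label) %in% have)) {
      stop("schedule lacks label ", start_label, " or ", end_label,
           " for treatment ", tr, call. = FALSE)
    }
  }
  ends <- ends |>
    dplyr::mutate(endpoint = ifelse(.data$label == start_label, "value_start",
                                    "value_end")) |>
    dplyr::select("treatment", "das", "endpoint")
  dt_tbl <- ends |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "das") |>
    dplyr::mutate(dt = .data$value_end - .data$value_start) |>
    dplyr::select("treatment", "dt")
  if (any(dt_tbl$dt <= 0)) {
    stop("window ", start_label, " -> ", end_label,
         " has non-positive elapsed time", call. = FALSE)
  }

  sub <- obs |>
    dplyr::filter(.data$trait == !!trait) |>
    dplyr::inner_join(ends, by = c("treatment", "das")) |>
    dplyr::select("genotype_id", "treatment", "block_id", "plot_id",
                  "plant_id", "endpoint", "value")
  wide <- sub |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "value")
  if (!"value_start" %in% names(wide)) wide$value_start <- NA_real_
  if (!"value_end" %in% names(wide)) wide$value_end <- NA_real_
  complete <- !is.na(wide$value_start) & !is.na(wide$value_end)
  out <- wide[complete, ] |>
    dplyr::inner_join(dt_tbl, by = "treatment") |>
    dplyr::select("genotype_id", "treatment", "block_id", "plot_id",
                  "plant_id", "value_start", "value_end", "dt")
  attr(out, "n_dropped") <- sum(!complete)
  out
}
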