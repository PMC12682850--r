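#' Classify root segments by diameter
#'
#' Flatbed-scanner diameter classes for rice root systems: S-type lateral
#' roots (thin, unbranched, determinate), L-type lateral roots (thicker,
#' longer, branch-capable) and axial roots (seminal and crown roots).
#' Boundaries are closed above: `d <= 0.15` is S-type, `0.15 < d <= 0.37`
#' is L-type, `d > 0.37` is axial. The cut points are configurable.
#'
#' @param diameter Segment diameters in mm, strictly positive. Vectorized.
#' @param boundaries Two increasing cut points in mm, default
#'   `c(0.15, 0.37)`.
#' @return A character vector in `{"S_type", "L_type", "axial"}`.
#' @export
#' @examples
#' classify_segment(c(0.10, 0.30, 0.50)) # S_type, L_type, axial
classify_segment <- function(diameter, boundaries = c(0.15, 0.37)) {
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2])
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("diameter must be finite and > 0", call. = FALSE)
  }
  ifelse(diameter <= boundaries[1], "S_type",
         ifelse(diameter <= boundaries[2], "L_type", "axial"))
}

#' Validate a root-segment table
#'
#' Segments carry `plant_id`, `segment_id`, `parent_segment_id` (`NA` marks
#' the base of an axial root), `length` and `diameter` in mm. Parent links
#' must form a forest within each plant: every parent exists and no cycles.
#'
#' @param segments A data frame of root segments.
#' @return The validated tibble.
#' @export
validate_segments <- function(segments) {
  required <- c("plant_id", "segment_id", "parent_segment_id",
                "length", "diameter")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  segments <- tibble::as_tibble(segments)
  if (any(!is.finite(segments$length)) || any(segments$length <= 0) ||
      any(!is.finite(segments$diameter)) || any(segments$diameter <= 0)) {
    stop("length and diameter must be finite and > 0", call. = FALSE)
  }
  for (pl in split(segments, segments$plant_id)) {
    if (anyDuplicated(pl$segment_id)) {
      stop("duplicate segment_id within plant ", pl$plant_id[1],
           call. = FALSE)
    }
    parent <- setNames(pl$parent_segment_id, pl$segment_id)
    known <- !is.na(parent) & !(parent %in% pl$segment_id)
    if (any(known)) {
      stop("unknown parent segment(s) in plant ", pl$plant_id[1], ": ",
           paste(head(parent[known], 3), collapse = ", "), call. = FALSE)
    }
    # cycle check: iteratively strip leaves; anything left lies on a cycle
    remaining <- pl$segment_id
    par <- parent
    repeat {
      is_parent <- remaining %in% par[remaining]
      leaves <- remaining[!is_parent]
      if (length(leaves) == 0) break
      remaining <- setdiff(remaining, leaves)
      if (length(remaining) == 0) break
    }
    if (length(remaining) > 0) {
      stop("cycle in root topology of plant ", pl$plant_id[1], call. = FALSE)
    }
  }
  segments
}

#' Read a root-segment CSV
#'
#' Columns `plant_id,segment_id,parent_segment_id,length_mm,diameter_mm`
#' plus optional metadata columns (genotype, treatment, timepoint ...) that
#' are carried through unchanged. An empty parent field marks the base of an
#' axial root.
#'
#' @param path Path to the CSV.
#' @return A validated segment tibble (`length`/`diameter` in mm).
#' @export
read_root_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seg <- readr::read_csv(path, col_types = readr::cols(
    plant_id = readr::col_character(), segment_id = readr::col_character(),
    parent_segment_id = readr::col_character(),
    length_mm = readr::col_double(), diameter_mm = readr::col_double(),
    .default = readr::col_character()), progress = FALSE)
  seg <- dplyr::rename(seg, length = "length_mm", diameter = "diameter_mm")
  validate_segments(seg)
}

#' Per-group root length by diameter class
#'
#' Sums segment length per diameter class within each group (by default per
#' plant) and derives class proportions. Class lengths always sum exactly to
#' the total input length (same summation over a partition); proportions are
#' flagged undefined when the total is zero (empty group).
#'
#' @param segments A validated segment tibble.
#' @param by Grouping columns, default `"plant_id"`.
#' @param boundaries Diameter cut points passed to [classify_segment()].
#' @return A tibble per group with `length_S`, `length_L`, `length_axial`,
#'   `length_total`, `prop_S`, `prop_L`, `prop_axial` and
#'   `proportions_defined`.
#' @export
summarize_root_types <- function(segments, by = "plant_id",
                                 boundaries = c(0.15, 0.37)) {
  segments <- validate_segments(segments)
  segments$class <- classify_segment(segments$diameter, boundaries)
  out <- segments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      length_S = sum(.data$length[.data$class == "S_type"]),
      length_L = sum(.data$length[.data$class == "L_type"]),
      length_axial = sum(.data$length[.data$class == "axial"]),
      .groups = "drop") |>
    # total as the sum of the class sums: the partition is exact by
    # construction, independent of floating summation order
    dplyr::mutate(length_total = .data$length_S + .data$length_L +
                    .data$length_axial)
  out |>
    dplyr::mutate(
      proportions_defined = .data$length_total > 0,
      prop_S = ifelse(.data$proportions_defined,
                      .data$length_S / .data$length_total, NA_real_),
      prop_L = ifelse(.data$proportions_defined,
                      .data$length_L / .data$length_total, NA_real_),
      prop_axial = ifelse(.data$proportions_defined,
                          .data$length_axial / .data$length_total, NA_real_))
}

#' Link analysis: external/internal link counts and mean S-type lateral length
#'
#' In scanner link terminology an external link is a root tip (a segment
#' with no children) and an internal link a branch-bearing segment. The
#' mean S-type lateral-root length is estimated as the total length of
#' S-class segments divided by the number of external links whose tip
#' segment is S-class; when every S-type lateral is a single unbranched
#' segment this is the exact mean, otherwise it is a tip-count estimator.
#'
#' @param segments A validated segment tibble.
#' @param by Grouping columns, default `"plant_id"`.
#' @param boundaries Diameter cut points passed to [classify_segment()].
#' @return Per group: `external_links`, `internal_links`, `n_segments`,
#'   `n_s_tips`, `mean_s_lr_length` (`NA` with `s_tips_present = FALSE`
#'   when no S-class tip exists).
#' @export
link_analysis <- function(segments, by = "plant_id",
                          boundaries = c(0.15, 0.37)) {
  segments <- validate_segments(segments)
  segments$class <- classify_segment(segments$diameter, boundaries)
  segments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(.link_stats(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

.link_stats <- function(pl) {
  is_internal <- pl$segment_id %in% pl$parent_segment_id
  s_tip <- !is_internal & pl$class == "S_type"
  n_s_tips <- sum(s_tip)
  tibble::tibble(
    external_links = sum(!is_internal),
    internal_links = sum(is_internal),
    n_segments = nrow(pl),
    n_s_tips = n_s_tips,
    s_tips_present = n_s_tips > 0,
    mean_s_lr_length = if (n_s_tips > 0) {
      sum(pl$length[pl$class == "S_type"]) / n_s_tips
    } else NA_real_)
}

#' Assign first or second order to lateral roots
#'
#' A lateral (non-axial) segment is first-order when its ancestor chain
#' reaches an axial-class segment without passing through an L-class
#' segment of a different lateral, and second-order when it branches off an
#' L-class lateral. Ancestors of the segment's own class are skipped as part
#' of the same lateral (a lateral may be a chain of segments). Axial
#' segments get `NA`; a non-axial segment with no parent is a structural
#' error.
#'
#' @param segments A validated segment tibble.
#' @param boundaries Diameter cut points passed to [classify_segment()].
#' @return `segments` with `class` and `lr_order` (`"first"`, `"second"`,
#'   or `NA` for axial segments) appended.
#' @export
assign_lr_order <- function(segments, boundaries = c(0.15, 0.37)) {
  segments <- validate_segments(segments)
  segments$class <- classify_segment(segments$diameter, boundaries)
  per_plant <- lapply(split(segments, segments$plant_id), function(pl) {
    parent <- setNames(pl$parent_segment_id, pl$segment_id)
    class <- setNames(pl$class, pl$segment_id)
    order_of <- function(sid) {
      own <- class[[sid]]
      cur <- parent[[sid]]
      repeat {
        if (is.na(cur)) {
          stop("lateral segment ", sid, " of plant ", pl$plant_id[1],
               " has no classified parent", call. = FALSE)
        }
        anc <- class[[cur]]
        if (anc == "axial") return("first")
        if (anc != own && anc == "L_type") return("second")
        # same lateral chain (same class) or an S-class pass-through: walk on
        cur <- parent[[cur]]
      }
    }
    pl$lr_order <- vapply(seq_len(nrow(pl)), function(i) {
      if (pl$class[i] == "axial") NA_character_ else order_of(pl$segment_id[i])
    }, character(1))
    pl
  })
  out <- dplyr::bind_rows(per_plant)
  out[order(match(paste(out$plant_id, out$segment_id),
                  paste(segments$plant_id, segments$segment_id))), ]
}

#' Aggregate root-longevity staining scores
#'
#' Staining photos are scored on six intensities (integers 0--5) per root
#' class. Aggregation is a two-stage unweighted mean: photos within root,
#' then roots within group (by default root class, treatment and
#' timepoint), reporting the sample sizes at both levels. Empty groups are
#' simply absent from the output.
#'
#' @param scores A tibble with `plant_id`, `root_id`, `root_class`,
#'   `photo_id`, `score` plus any grouping metadata columns.
#' @param by Grouping columns, default
#'   `c("root_class", "treatment", "timepoint")`.
#' @return Per group: `mean_score`, `n_roots`, `n_photos`.
#' @export
aggregate_longevity <- function(scores,
                                by = c("root_class", "treatment", "timepoint")) {
  required <- c("plant_id", "root_id", "root_class", "photo_id", "score")
  missing_cols <- setdiff(c(required, by), names(scores))
  if (length(missing_cols) > 0) {
    stop("longevity table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!scores$score %in% 0:5)) {
    stop("scores must be integers in 0..5 (six intensities)", call. = FALSE)
  }
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      unique(c(by, "plant_id", "root_id"))))) |>
    dplyr::summarise(root_mean = mean(.data$score), n_photos = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_score = mean(.data$root_mean),
                     n_roots = dplyr::n(), n_photos = sum(.data$n_photos),
                     .groups = "drop")
}
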