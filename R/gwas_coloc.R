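#' Validate a GWAS summary table
#'
#' One row per association test: `season`, `snp_id`, `chrom`, `pos` (bp,
#' 1-based), `pvalue` in (0, 1], optional `maf` in \[0, 0.5\].
#'
#' @param hits A data frame of per-season association summary rows.
#' @return The validated tibble (with a `maf` column of `NA` if absent).
#' @export
validate_gwas_hits <- function(hits) {
  required <- c("season", "snp_id", "chrom", "pos", "pvalue")
  missing_cols <- setdiff(required, names(hits))
  if (length(missing_cols) > 0) {
    stop("GWAS table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  hits <- tibble::as_tibble(hits)
  if (!"maf" %in% names(hits)) hits$maf <- NA_real_
  if (any(!is.finite(hits$pos)) || any(hits$pos < 1) ||
      any(hits$pos != round(hits$pos))) {
    stop("pos must be a 1-based integer coordinate", call. = FALSE)
  }
  if (any(!is.finite(hits$pvalue)) || any(hits$pvalue <= 0) ||
      any(hits$pvalue > 1)) {
    stop("pvalue must lie in (0, 1]", call. = FALSE)
  }
  maf <- hits$maf[!is.na(hits$maf)]
  if (any(maf < 0 | maf > 0.5)) {
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  }
  hits
}

#' Read a per-season GWAS summary CSV
#'
#' Columns `season,snp_id,chrom,pos,pvalue[,maf]`.
#'
#' @param path Path to the CSV.
#' @param season Optional season label overriding / filling the column.
#' @return A validated tibble of hits.
#' @export
read_gwas_table <- function(path, season = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hits <- readr::read_csv(path, col_types = readr::cols(
    season = readr::col_character(), snp_id = readr::col_character(),
    chrom = readr::col_character(), pos = readr::col_double(),
    pvalue = readr::col_double(), .default = readr::col_double()),
    progress = FALSE)
  if (!is.null(season)) hits$season <- as.character(season)
  validate_gwas_hits(hits)
}

#' Filter GWAS hits on -log10(p) and minor allele frequency
#'
#' Retains hits with `-log10(pvalue) >= min_neglog10p` (boundary inclusive:
#' p = 1e-3 passes the default threshold of 3) and, where a MAF is recorded,
#' `maf >= min_maf`. Hits without a MAF are not MAF-filtered. The numbers
#' removed per criterion are attached as attribute `n_removed`.
#'
#' @param hits A validated hit table.
#' @param min_neglog10p Minimum -log10(p), default 3.
#' @param min_maf Minimum minor allele frequency, default 0.05.
#' @return The retained hits, with attribute
#'   `n_removed = list(pvalue = , maf = )`.
#' @export
filter_hits <- function(hits, min_neglog10p = 3, min_maf = 0.05) {
  hits <- validate_gwas_hits(hits)
  keep_p <- -log10(hits$pvalue) >= min_neglog10p
  keep_maf <- is.na(hits$maf) | hits$maf >= min_maf
  out <- hits[keep_p & keep_maf, ]
  attr(out, "n_removed") <- list(pvalue = sum(!keep_p),
                                 maf = sum(keep_p & !keep_maf))
  out
}

#' Flag genome-wide-significant hits
#'
#' Adds a logical `significant` column: `pvalue < alpha`, strict inequality,
#' with no multiple-testing correction (matching how such field-season scans
#' are conventionally reported at a fixed nominal threshold).
#'
#' @param hits A validated hit table.
#' @param alpha Significance threshold, default 1e-4.
#' @return `hits` with a `significant` column appended.
#' @export
flag_significant <- function(hits, alpha = 1e-4) {
  hits <- validate_gwas_hits(hits)
  hits$significant <- hits$pvalue < alpha
  hits
}

#' Find peaks co-locating across seasons
#'
#' Single-linkage clustering of hit positions per chromosome with linkage
#' distance `<= window_bp` (inclusive: two hits exactly `window_bp` apart
#' are linked). Clusters are retained only when their members span at least
#' two distinct seasons — the signature of a reproducible peak. On a line
#' (positions on one chromosome), single-linkage components are exactly the
#' runs obtained by splitting sorted positions at gaps larger than
#' `window_bp`.
#'
#' @param hits Filtered hits (apply [filter_hits()] first).
#' @param window_bp Co-location window in bp, default 100000.
#' @return A tibble, ordered by (chrom, interval start), with `cluster_id`,
#'   `chrom`, `start`, `end`, `n_hits`, `n_seasons`, `seasons`
#'   (comma-separated) and a list-column `members` of the member hits.
#' @export
find_colocations <- function(hits, window_bp = 100000) {
  hits <- validate_gwas_hits(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(cluster_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_hits = integer(), n_seasons = integer(),
                          seasons = character(), members = list()))
  }
  hits <- hits[order(hits$chrom, hits$pos, hits$season, hits$snp_id), ]
  new_chrom <- c(TRUE, hits$chrom[-1] != hits$chrom[-nrow(hits)])
  gap <- c(Inf, diff(hits$pos))
  hits$.comp <- cumsum(new_chrom | gap > window_bp)

  comps <- split(hits, hits$.comp)
  keep <- vapply(comps, function(m) length(unique(m$season)) >= 2, logical(1))
  comps <- comps[keep]
  if (length(comps) == 0) {
    return(find_colocations(hits[0, setdiff(names(hits), ".comp")], window_bp))
  }
  out <- dplyr::bind_rows(lapply(comps, function(m) {
    seasons <- sort(unique(m$season))
    tibble::tibble(chrom = m$chrom[1], start = min(m$pos), end = max(m$pos),
                   n_hits = nrow(m), n_seasons = length(seasons),
                   seasons = paste(seasons, collapse = ","),
                   members = list(m[setdiff(names(m), ".comp")]))
  }))
  out <- out[order(out$chrom, out$start), ]
  out$cluster_id <- sprintf("coloc_%03d", seq_len(nrow(out)))
  out[, c("cluster_id", "chrom", "start", "end", "n_hits", "n_seasons",
          "seasons", "members")]
}

#' Validate a gene annotation table
#'
#' Minimal annotation: `gene_id`, `chrom`, `start`, `end` (bp, 1-based,
#' closed), optional `description`.
#'
#' @param annotation A data frame of gene features.
#' @return The validated tibble.
#' @export
validate_annotation <- function(annotation) {
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  annotation <- tibble::as_tibble(annotation)
  if (!"description" %in% names(annotation)) {
    annotation$description <- NA_character_
  }
  if (any(annotation$start > annotation$end)) {
    stop("annotation has start > end", call. = FALSE)
  }
  annotation
}

#' Read a gene annotation from GFF3 or CSV
#'
#' GFF3 files (`.gff`/`.gff3`) are parsed with rtracklayer, keeping
#' `type == "gene"` features and taking the gene id from the `ID` attribute;
#' coordinates stay 1-based inclusive. Any other extension is read as a
#' minimal CSV with columns `gene_id,chrom,start,end[,description]`.
#'
#' @param path Path to the annotation file.
#' @return A validated annotation tibble.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", ]
    ann <- tibble::tibble(
      gene_id = as.character(gr$ID),
      chrom = as.character(gr$seqnames),
      start = gr$start,
      end = gr$end,
      description = if (!is.null(gr$description)) as.character(gr$description)
                    else NA_character_)
  } else {
    ann <- readr::read_csv(path, col_types = readr::cols(
      gene_id = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()), progress = FALSE)
  }
  validate_annotation(ann)
}

#' Candidate genes in a flanking window around peaks
#'
#' For each co-location cluster (or single hit), returns the genes whose
#' `[start, end]` interval overlaps `[interval_min - flank_bp,
#' interval_max + flank_bp]` on the same chromosome. All intervals are
#' closed and overlap is inclusive: a gene ending exactly at
#' `interval_min - flank_bp` is included.
#'
#' @param x Either a cluster table from [find_colocations()] or a hit table
#'   (each hit treated as a zero-width interval at its position).
#' @param annotation A validated annotation tibble.
#' @param flank_bp Flanking window in bp, default 100000.
#' @return A tibble of (query id, gene) rows: `query_id`, `chrom`,
#'   `gene_id`, `gene_start`, `gene_end`, `description`.
#' @export
genes_in_window <- function(x, annotation, flank_bp = 100000) {
  annotation <- validate_annotation(annotation)
  if (all(c("cluster_id", "start", "end") %in% names(x))) {
    q <- tibble::tibble(query_id = x$cluster_id, chrom = x$chrom,
                        lo = x$start - flank_bp, hi = x$end + flank_bp)
  } else if (all(c("snp_id", "pos") %in% names(x))) {
    q <- tibble::tibble(query_id = x$snp_id, chrom = x$chrom,
                        lo = x$pos - flank_bp, hi = x$pos + flank_bp)
  } else {
    stop("x must be a cluster table or a GWAS hit table", call. = FALSE)
  }
  out <- q |>
    dplyr::inner_join(annotation, by = "chrom",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$hi, .data$end >= .data$lo) |>
    dplyr::transmute(query_id = .data$query_id, chrom = .data$chrom,
                     gene_id = .data$gene_id, gene_start = .data$start,
                     gene_end = .data$end, description = .data$description)
  out[order(out$query_id, out$chrom, out$gene_start), ]
}
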