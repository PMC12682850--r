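# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# All-pairs + connected-components single-linkage clustering of GWAS hits.
# Returns a list of row-index sets (into `hits`), one per retained cluster
# (same chromosome, linkage distance <= window_bp, >= 2 distinct seasons).
oracle_coloc <- function(hits, window_bp) {
  n <- nrow(hits)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- hits$chrom[i] == hits$chrom[j] &&
        abs(hits$pos[i] - hits$pos[j]) <= window_bp
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier) > 0) {
        nxt <- which(adj[frontier[1], ] & is.na(comp))
        comp[nxt] <- cur
        frontier <- c(frontier[-1], nxt)
      }
    }
  }
  comps <- split(seq_len(n), comp)
  Filter(function(idx) length(unique(hits$season[idx])) >= 2, comps)
}

# Canonical form for comparing cluster outputs: sorted member snp_id strings.
cluster_signature <- function(member_sets, hits) {
  unname(sort(vapply(member_sets, function(idx) {
    paste(sort(hits$snp_id[idx]), collapse = "|")
  }, character(1))))
}

# Naive overlap scan for candidate genes around an interval.
oracle_genes <- function(chrom, lo, hi, annotation) {
  keep <- logical(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    keep[i] <- annotation$chrom[i] == chrom &&
      annotation$start[i] <= hi && annotation$end[i] >= lo
  }
  sort(annotation$gene_id[keep])
}

# Recursive root-to-tip path walk assigning lateral order, independent of
# the vectorized implementation: skip ancestors of the segment's own class,
# then classify by the first class-changing ancestor (axial -> first,
# L_type -> second, otherwise keep walking).
oracle_lr_order <- function(segments) {
  cls <- classify_segment(segments$diameter)
  parent <- setNames(segments$parent_segment_id,
                     paste(segments$plant_id, segments$segment_id))
  class_of <- setNames(cls, paste(segments$plant_id, segments$segment_id))
  walk <- function(plant, sid, own) {
    key <- paste(plant, sid)
    p <- parent[[key]]
    if (is.na(p)) stop("no classified parent")
    anc <- class_of[[paste(plant, p)]]
    if (anc == "axial") return("first")
    if (anc == "L_type" && own != "L_type") return("second")
    walk(plant, p, own)
  }
  vapply(seq_len(nrow(segments)), function(i) {
    if (cls[i] == "axial") return(NA_character_)
    walk(segments$plant_id[i], segments$segment_id[i], cls[i])
  }, character(1))
}

# Small well-formed phenotype table builder for io tests.
make_pheno <- function(n_geno = 2, das = c(34, 37), treatment = "drought",
                       trait = "leaf_length_total", value_fun = function(i, d) 10 + d + i) {
  grid <- expand.grid(genotype_id = sprintf("G%02d", seq_len(n_geno)),
                      plot = 1:2, plant = 1:2, das = das,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    genotype_id = grid$genotype_id,
    treatment = treatment,
    block_id = sprintf("B%d", grid$plot),
    plot_id = sprintf("p%d", grid$plot),
    plant_id = sprintf("P%d", grid$plant),
    das = grid$das,
    trait = trait,
    value = value_fun(as.integer(factor(grid$genotype_id)), grid$das))
}

# Random validated phenotype table for round-trip property tests.
random_pheno <- function(seed) {
  withr::with_seed(seed, {
    n_geno <- sample(1:4, 1)
    das <- sort(sample(1:60, sample(2:4, 1)))
    trait <- sample(setdiff(TRAITS <- c("leaf_length_total", "shoot_dry_weight",
                                        "root_dry_weight", "root_length_total",
                                        "leaf_area"), NULL), 1)
    tab <- make_pheno(n_geno, das, sample(c("drought", "well_watered"), 1),
                      trait, value_fun = function(i, d) round(runif(length(i), 0, 50), 6))
    tab
  })
}
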