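make_hits <- function(pos, season, chrom = "3", pvalue = 1e-4, maf = NA_real_) {
  tibble::tibble(season = season, snp_id = sprintf("s%03d", seq_along(pos)),
                 chrom = chrom, pos = pos, pvalue = pvalue, maf = maf)
}

test_that("filtering keeps -log10 p >= threshold (inclusive) and maf >= cutoff", {
  hits <- make_hits(c(1e6, 2e6, 3e6), "2017",
                    pvalue = c(1e-3, 2e-3, 1e-5), maf = c(0.2, 0.2, 0.04))
  out <- filter_hits(hits)
  expect_equal(out$snp_id, "s001")  # 1e-3 boundary retained; 2e-3 and maf 0.04 removed
  expect_equal(attr(out, "n_removed")$pvalue, 1L)
  expect_equal(attr(out, "n_removed")$maf, 1L)

  # hits without maf are not maf-filtered
  nomaf <- filter_hits(make_hits(1e6, "2017", pvalue = 1e-4))
  expect_equal(nrow(nomaf), 1L)

  # brute-force equivalence on uniform p-values
  withr::with_seed(11, {
    p <- runif(1000)
    hits <- make_hits(seq_len(1000) * 1e4, "2018", pvalue = p)
    expect_equal(filter_hits(hits)$snp_id, hits$snp_id[-log10(p) >= 3])
  })
})

test_that("significance flag is strict p < alpha", {
  hits <- make_hits(c(1e6, 2e6), "2017", pvalue = c(1e-4, 9.9e-5))
  expect_equal(flag_significant(hits)$significant, c(FALSE, TRUE))
  withr::with_seed(12, {
    p <- runif(500)
    hits <- make_hits(seq_len(500) * 1e4, "2019", pvalue = p)
    expect_equal(sum(flag_significant(hits, 0.05)$significant), sum(p < 0.05))
  })
})

test_that("two-hit co-location follows the inclusive 100-kb rule", {
  two <- make_hits(c(1000000, 1050000), c("2017", "2018"))
  cl <- find_colocations(two)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(1000000, 1050000))

  # same season never forms a cluster
  expect_equal(nrow(find_colocations(make_hits(c(1e6, 1.05e6), "2017"))), 0L)

  # boundary: exactly window_bp clusters, one more bp does not
  expect_equal(nrow(find_colocations(make_hits(c(1e6, 1.1e6), c("2017", "2018")))), 1L)
  expect_equal(nrow(find_colocations(make_hits(c(1e6, 1.1e6 + 1), c("2017", "2018")))), 0L)

  # different chromosomes never link
  split_chr <- make_hits(c(1e6, 1.02e6), c("2017", "2018"))
  split_chr$chrom <- c("3", "4")
  expect_equal(nrow(find_colocations(split_chr)), 0L)
})

test_that("clustering equals the all-pairs connected-components oracle", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      n <- sample(10:100, 1)
      hits <- tibble::tibble(
        season = sample(c("2017", "2018", "2019"), n, replace = TRUE),
        snp_id = sprintf("s%03d", seq_len(n)),
        chrom = sample(c("1", "2"), n, replace = TRUE),
        pos = sample(1:3000000, n),
        pvalue = runif(n, 1e-6, 1e-3))
      got <- find_colocations(hits, window_bp = 100000)
      want <- oracle_coloc(hits, window_bp = 100000)
      got_sig <- sort(vapply(got$members, function(m) {
        paste(sort(m$snp_id), collapse = "|")
      }, character(1)))
      expect_equal(got_sig, cluster_signature(want, hits))
    })
  }
})

test_that("clustering is permutation-invariant and monotone in window size", {
  withr::with_seed(99, {
    hits <- tibble::tibble(
      season = sample(c("2017", "2018", "2019"), 60, replace = TRUE),
      snp_id = sprintf("s%03d", 1:60), chrom = sample(c("1", "2"), 60, TRUE),
      pos = sample(1:2000000, 60), pvalue = runif(60, 1e-6, 1e-3))
    a <- find_colocations(hits)
    b <- find_colocations(hits[sample(60), ])
    expect_equal(a[setdiff(names(a), "members")], b[setdiff(names(b), "members")])
    # members partition: each retained hit in at most one cluster
    ids <- unlist(lapply(a$members, function(m) m$snp_id))
    expect_equal(anyDuplicated(ids), 0L)
    # shrinking the window never grows membership
    small <- find_colocations(hits, window_bp = 20000)
    expect_lte(sum(small$n_hits), sum(a$n_hits))
  })
})

test_that("candidate gene extraction matches a brute-force overlap scan", {
  withr::with_seed(21, {
    ann <- tibble::tibble(
      gene_id = sprintf("LOC_Os%05d", 1:500),
      chrom = sample(c("1", "2", "3"), 500, replace = TRUE),
      start = sample(1:5000000, 500))
    ann$end <- ann$start + sample(500:20000, 500, replace = TRUE)
    clusters <- tibble::tibble(cluster_id = c("c1", "c2"),
                               chrom = c("1", "3"),
                               start = c(1200000, 2500000),
                               end = c(1300000, 2500000))
    got <- genes_in_window(clusters, ann, flank_bp = 100000)
    for (i in 1:2) {
      want <- oracle_genes(clusters$chrom[i], clusters$start[i] - 100000,
                           clusters$end[i] + 100000, ann)
      expect_equal(sort(got$gene_id[got$query_id == clusters$cluster_id[i]]),
                   want)
    }
  })

  # closed-interval boundary: gene ending exactly at pos - flank is included
  ann <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "5",
                        start = c(850000, 700000, 1100000),
                        end = c(900000, 800000, 1200000))
  hit <- tibble::tibble(snp_id = "s1", chrom = "5", pos = 1000000)
  got <- genes_in_window(hit, ann, flank_bp = 100000)
  expect_setequal(got$gene_id, c("gA", "gC"))
  # other chromosome excluded
  ann$chrom[3] <- "6"
  expect_setequal(genes_in_window(hit, ann, 100000)$gene_id, "gA")
})

test_that("GWAS tables and annotations round-trip through their readers", {
  hits <- make_hits(c(1e6, 2e6), c("2017", "2018"), pvalue = c(1e-4, 2e-5),
                    maf = c(0.1, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(hits, path)
  expect_equal(as.data.frame(read_gwas_table(path)), as.data.frame(hits))

  ann <- tibble::tibble(gene_id = "g1", chrom = "1", start = 100L,
                        end = 200L, description = "kinase")
  apath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ann, apath)
  expect_equal(read_gene_annotation(apath)$gene_id, "g1")

  bad <- hits
  bad$pvalue[1] <- 0
  bpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, bpath)
  expect_error(read_gwas_table(bpath), "pvalue")
})
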