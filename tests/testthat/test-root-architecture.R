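# small hand-built root system: one axial root with S and L laterals,
# one 2nd-order S lateral branching off the L
hand_system <- function() {
  tibble::tibble(
    plant_id = "p1",
    segment_id = c("A1", "S1", "S2", "S3", "L1", "L1_S1"),
    parent_segment_id = c(NA, "A1", "A1", "A1", "A1", "L1"),
    length = c(150, 5, 7, 9, 40, 4),
    diameter = c(0.5, 0.10, 0.12, 0.08, 0.25, 0.09))
}

test_that("diameter classification uses closed upper boundaries", {
  expect_equal(classify_segment(c(0.10, 0.30, 0.50)),
               c("S_type", "L_type", "axial"))
  expect_equal(classify_segment(c(0.15, 0.37)), c("S_type", "L_type"))
  expect_equal(classify_segment(0.150001), "L_type")
  expect_error(classify_segment(0), "> 0")
  # configurable boundaries
  expect_equal(classify_segment(0.2, boundaries = c(0.25, 0.5)), "S_type")
})

test_that("class lengths partition the total exactly and proportions sum to 1", {
  seg <- tibble::tibble(plant_id = "p1", segment_id = c("a", "b", "c"),
                        parent_segment_id = c(NA, "a", "a"),
                        length = c(70, 20, 10), diameter = c(0.5, 0.2, 0.1))
  s <- summarize_root_types(seg)
  expect_equal(c(s$prop_S, s$prop_L, s$prop_axial), c(0.1, 0.2, 0.7))
  expect_equal(s$length_S + s$length_L + s$length_axial, s$length_total)

  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(5:80, 1)
      seg <- tibble::tibble(
        plant_id = sample(c("p1", "p2"), n, replace = TRUE),
        segment_id = sprintf("s%03d", seq_len(n)),
        parent_segment_id = NA_character_,
        length = runif(n, 0.1, 50), diameter = runif(n, 0.01, 1))
      s <- summarize_root_types(seg)
      totals <- tapply(seg$length, seg$plant_id, sum)
      expect_identical(s$length_S + s$length_L + s$length_axial,
                       s$length_total)
      expect_equal(s$length_total, as.vector(totals[s$plant_id]))
      expect_true(all(abs(s$prop_S + s$prop_L + s$prop_axial - 1) <= 1e-9))
    })
  }
})

test_that("link analysis counts tips and recovers mean S-lateral length", {
  seg <- tibble::tibble(plant_id = "p1",
                        segment_id = c("A1", "S1", "S2", "S3"),
                        parent_segment_id = c(NA, "A1", "A1", "A1"),
                        length = c(150, 5, 7, 9),
                        diameter = c(0.5, 0.1, 0.1, 0.1))
  la <- link_analysis(seg)
  expect_equal(la$external_links, 3L)  # 3 S tips; the axial bears children
  expect_equal(la$internal_links, 1L)
  expect_equal(la$mean_s_lr_length, 7)
  expect_equal(la$external_links + la$internal_links, la$n_segments)

  # a 2nd-order S lateral off an L lateral is the only S tip
  seg2 <- hand_system()[c(1, 5, 6), ]
  la2 <- link_analysis(seg2)
  expect_equal(la2$n_s_tips, 1L)
  expect_equal(la2$mean_s_lr_length, 4)

  # no S tips -> undefined marker, not an error
  seg3 <- seg2[1:2, ]
  la3 <- link_analysis(seg3)
  expect_false(la3$s_tips_present)
  expect_true(is.na(la3$mean_s_lr_length))
})

test_that("cycles in topology are rejected", {
  seg <- tibble::tibble(plant_id = "p1", segment_id = c("a", "b"),
                        parent_segment_id = c("b", "a"),
                        length = c(1, 1), diameter = c(0.1, 0.1))
  expect_error(link_analysis(seg), "cycle")
})

test_that("lateral order matches the recursive path-walk oracle", {
  seg <- assign_lr_order(hand_system())
  expect_equal(setNames(seg$lr_order, seg$segment_id),
               c(A1 = NA, S1 = "first", S2 = "first", S3 = "first",
                 L1 = "first", L1_S1 = "second"))

  for (seed in 1:20) {
    sys <- gen_root_system(root_sim_config(seed = seed),
                           condition = sample(c("well_watered", "drought"), 1))
    got <- assign_lr_order(sys$segments)
    expect_equal(got$lr_order, oracle_lr_order(got))
  }

  orphan <- tibble::tibble(plant_id = "p1", segment_id = "s1",
                           parent_segment_id = NA, length = 5, diameter = 0.1)
  expect_error(assign_lr_order(orphan), "no classified parent")
})

test_that("longevity scores aggregate photos within root then roots within group", {
  scores <- tibble::tibble(
    plant_id = "p1", root_class = "S_type", treatment = "drought",
    timepoint = "M2", root_id = c("r1", "r1", "r2"),
    photo_id = c("f1", "f2", "f3"), score = c(2, 4, 5))
  agg <- aggregate_longevity(scores)
  expect_equal(agg$mean_score, mean(c(3, 5)))
  expect_equal(agg$n_roots, 2L)
  expect_equal(agg$n_photos, 3L)

  expect_equal(aggregate_longevity(
    dplyr::mutate(scores, score = 5))$mean_score, 5)

  # permutation invariance
  perm <- scores[c(3, 1, 2), ]
  expect_equal(aggregate_longevity(perm), aggregate_longevity(scores))

  bad <- dplyr::mutate(scores, score = c(2, 4, 6))
  expect_error(aggregate_longevity(bad), "0..5")
})

test_that("segment tables round-trip through the CSV reader", {
  seg <- hand_system()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::rename(seg, length_mm = length,
                                 diameter_mm = diameter), path)
  back <- read_root_segments(path)
  expect_equal(as.data.frame(back), as.data.frame(seg))
})
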