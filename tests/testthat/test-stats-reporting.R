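test_that("centring subtracts the group mean", {
  expect_equal(center_to_zero_mean(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_to_zero_mean(rep(4, 5)), rep(0, 5))
  withr::with_seed(8, {
    x <- rnorm(50, mean = 3)
    expect_equal(mean(center_to_zero_mean(x)), 0, tolerance = 1e-12)
  })
  expect_error(center_to_zero_mean(numeric(0)), "empty")
})

test_that("one-sample t matches the closed form and the reference implementation", {
  r <- one_sample_t(c(-1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)

  r2 <- one_sample_t(c(1, 2, 3))
  expect_equal(r2$statistic, 2 * sqrt(3))
  expect_equal(r2$df, 2)

  for (seed in 1:20) {
    withr::with_seed(seed, {
      x <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      mu <- runif(1, -0.5, 0.5)
      ref <- t.test(x, mu = mu)
      got <- one_sample_t(x, mu = mu)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$pvalue, ref$p.value, tolerance = 1e-10)
    })
  }

  const <- one_sample_t(c(2, 2, 2))
  expect_true(is.na(const$statistic) && is.na(const$pvalue))
})

test_that("Type II ANOVA matches a hand-built SS decomposition on a balanced 2x2", {
  # balanced 2x2 with 2 replicates per cell, known cell means, zero noise
  d <- expand.grid(g = c("g1", "g2"), tr = c("d", "w"), rep = 1:2)
  cell_means <- c(g1.d = 10, g2.d = 14, g1.w = 12, g2.w = 20)
  d$y <- cell_means[paste(d$g, d$tr, sep = ".")]
  got <- two_way_anova_typeII(d$y, d$g, d$tr)

  # brute-force sums of squares for the balanced case
  grand <- mean(d$y)
  ss_g <- sum(tapply(d$y, d$g, function(v) length(v) * (mean(v) - grand)^2))
  ss_t <- sum(tapply(d$y, d$tr, function(v) length(v) * (mean(v) - grand)^2))
  cellm <- tapply(d$y, paste(d$g, d$tr), mean)
  ss_cells <- sum(2 * (cellm - grand)^2)
  ss_int <- ss_cells - ss_g - ss_t
  expect_equal(got$sumsq[got$term == "genotype"], ss_g)
  expect_equal(got$sumsq[got$term == "treatment"], ss_t)
  expect_equal(got$sumsq[got$term == "genotype:treatment"], ss_int)
  # zero residual -> undefined F marker
  expect_true(all(is.na(got$statistic[got$term != "Residuals"])))
})

test_that("Type II agrees with car::Anova and equals Type I when balanced", {
  skip_if_not_installed("car")
  for (seed in 1:15) {
    withr::with_seed(seed, {
      ng <- sample(2:4, 1)
      d <- expand.grid(g = paste0("g", 1:ng), tr = c("d", "w"), rep = 1:3)
      d$y <- rnorm(nrow(d), mean = as.integer(factor(d$g)))
      got <- two_way_anova_typeII(d$y, d$g, d$tr)
      fit <- stats::lm(y ~ g * tr, data = d)
      ref <- car::Anova(fit, type = 2)
      expect_equal(got$sumsq[1:3], ref[["Sum Sq"]][1:3], tolerance = 1e-9)
      expect_equal(got$pvalue[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-9)
      # balanced: sequential SS identical
      seq_ss <- stats::anova(fit)[["Sum Sq"]]
      expect_equal(got$sumsq[1:3], seq_ss[1:3], tolerance = 1e-9)
    })
  }
})

test_that("aliased designs and constant responses are handled", {
  d <- expand.grid(g = c("g1", "g2"), tr = c("d", "w"), rep = 1:2)
  expect_error(two_way_anova_typeII(rnorm(4), c("g1", "g1", "g2", "g2"),
                                    c("d", "d", "w", "w")),
               "replication|aliased")
  got <- two_way_anova_typeII(rep(5, nrow(d)), d$g, d$tr)
  expect_true(all(is.na(got$statistic[1:3])))
})

test_that("Tukey HSD agrees with stats::TukeyHSD on random balanced one-way designs", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      k <- sample(3:5, 1)
      n <- sample(4:8, 1)
      d <- data.frame(grp = factor(rep(paste0("g", 1:k), each = n)))
      d$y <- rnorm(nrow(d), mean = as.integer(d$grp) * runif(1, 0, 1.5))
      fit <- stats::aov(y ~ grp, data = d)
      ref <- stats::TukeyHSD(fit)$grp
      means <- tapply(d$y, d$grp, mean)
      mse <- sum(stats::residuals(fit)^2) / fit$df.residual
      got <- tukey_hsd(means, mse, n)
      key <- paste(got$comparisons$group2, got$comparisons$group1, sep = "-")
      expect_equal(got$comparisons$p_adj, unname(ref[key, "p adj"]),
                   tolerance = 1e-8)
      expect_equal(got$comparisons$diff, unname(ref[key, "diff"]),
                   tolerance = 1e-10)
    })
  }
})

test_that("compact letters separate clearly different groups and join identical ones", {
  res <- tukey_hsd(c(a = 10, b = 10.01), mse = 1, n = 10)
  expect_equal(unname(res$letters), c("a", "a"))

  res2 <- tukey_hsd(c(a = 0, b = 50), mse = 0.5, n = 10)
  expect_true(res2$comparisons$significant)
  expect_false(res2$letters["a"] == res2$letters["b"])

  res3 <- tukey_hsd(c(lo = 0, mid = 5, hi = 10), mse = 0.4, n = 6)
  expect_equal(length(unique(res3$letters)), 3L)
})

test_that("the pipeline writes deterministic outputs and honours feature flags", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- field_sim_config(n_genotypes = 6, strategy = seq(0, 1, length.out = 6))
  res <- run_pipeline(out1, seed = 9, field_config = cfg,
                      root_config = root_sim_config(n_axial = 2, s_per_axial = 8))
  expect_equal(nrow(res$wri), 6L)
  expect_true(file.exists(file.path(out1, "wri.csv")))
  expect_true(file.exists(file.path(out1, "root_type_summary.csv")))
  expect_false(file.exists(file.path(out1, "coloc_clusters.csv")))

  run_pipeline(out2, seed = 9, field_config = cfg,
               root_config = root_sim_config(n_axial = 2, s_per_axial = 8))
  for (f in c("phenotypes.csv", "wri.csv", "line_rates.csv",
              "root_type_summary.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
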