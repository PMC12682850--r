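#' Centre values to zero mean
#'
#' Used before one-sample t-tests on growth rates so genotypic deviations
#' from the experiment mean are tested against zero.
#'
#' @param values Non-empty numeric vector.
#' @return `values - mean(values)`.
#' @export
center_to_zero_mean <- function(values) {
  if (length(values) == 0) stop("cannot centre an empty vector", call. = FALSE)
  values - mean(values)
}

#' One-sample t-test
#'
#' Classical two-sided one-sample t: `t = (mean - mu) / (sd / sqrt(n))`,
#' `df = n - 1`. Zero variance yields an undefined-result marker (`NA`
#' statistic and p) rather than an error.
#'
#' @param values Numeric vector, `n >= 2`, all finite.
#' @param mu Null mean, default 0.
#' @return A one-row tibble: `test`, `statistic`, `df`, `pvalue`, `n`,
#'   `estimate`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  n <- length(values)
  s <- sd(values)
  if (s == 0) {
    return(tibble::tibble(test = "one_sample_t", statistic = NA_real_,
                          df = n - 1, pvalue = NA_real_, n = n,
                          estimate = mean(values)))
  }
  tstat <- (mean(values) - mu) / (s / sqrt(n))
  tibble::tibble(test = "one_sample_t", statistic = tstat, df = n - 1,
                 pvalue = 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE),
                 n = n, estimate = mean(values))
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Type II tests each main effect adjusted for the other main effect
#' (ignoring the interaction) and the interaction adjusted for both main
#' effects, assembled from residual sums of squares of nested linear-model
#' fits. On balanced designs Type II coincides with sequential (Type I)
#' sums of squares.
#'
#' @param response Numeric response vector.
#' @param factor_genotype,factor_treatment Factor (or coercible) vectors.
#' @return A tibble with one row per term (`genotype`, `treatment`,
#'   `genotype:treatment`, `Residuals`): `df`, `sumsq`, `statistic`
#'   (F, `NA` for residuals), `pvalue`.
#' @export
two_way_anova_typeII <- function(response, factor_genotype, factor_treatment) {
  g <- factor(factor_genotype)
  tr <- factor(factor_treatment)
  if (nlevels(g) < 2 || nlevels(tr) < 2) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  d <- data.frame(y = response, g = g, tr = tr)
  rss <- function(form) {
    fit <- stats::lm(form, data = d)
    list(rss = sum(stats::residuals(fit)^2), edf = fit$df.residual)
  }
  full <- rss(y ~ g * tr)
  add <- rss(y ~ g + tr)
  only_g <- rss(y ~ g)
  only_tr <- rss(y ~ tr)
  if (full$edf < 1) {
    stop("no residual degrees of freedom: genotype:treatment cells need ",
         "replication", call. = FALSE)
  }
  ss <- c(genotype = only_tr$rss - add$rss,
          treatment = only_g$rss - add$rss,
          `genotype:treatment` = add$rss - full$rss)
  df <- c(genotype = only_tr$edf - add$edf,
          treatment = only_g$edf - add$edf,
          `genotype:treatment` = add$edf - full$edf)
  if (any(df == 0)) {
    stop("aliased term: ", paste(names(df)[df == 0], collapse = ", "),
         call. = FALSE)
  }
  mse <- full$rss / full$edf
  total_ss <- sum((d$y - mean(d$y))^2)
  if (full$rss <= 1e-12 * max(total_ss, 1)) {
    # saturated or constant response: F undefined
    fstat <- rep(NA_real_, 3)
    pval <- rep(NA_real_, 3)
  } else {
    fstat <- (ss / df) / mse
    pval <- pf(fstat, df, full$edf, lower.tail = FALSE)
  }
  tibble::tibble(
    term = c(names(ss), "Residuals"),
    df = unname(c(df, full$edf)),
    sumsq = unname(c(ss, full$rss)),
    statistic = unname(c(fstat, NA_real_)),
    pvalue = unname(c(pval, NA_real_)))
}

#' Tukey honestly-significant-difference comparisons with compact letters
#'
#' Pairwise studentized-range comparisons from group means, the ANOVA mean
#' squared error and group sizes:
#' `q = |m_i - m_j| / sqrt((mse / 2) * (1/n_i + 1/n_j))`, with the adjusted
#' p-value from the studentized range distribution on (k, df_error). Groups
#' are summarised by a compact letter display (insert-and-absorb): groups
#' sharing a letter do not differ at `alpha`.
#'
#' @param means Named numeric vector of group means (>= 2 groups).
#' @param mse Residual mean square from the fitted ANOVA.
#' @param n Group sizes: scalar or named vector aligned with `means`.
#' @param alpha Familywise significance level, default 0.05.
#' @param df_error Residual degrees of freedom; default `sum(n) - k`.
#' @return A list: `comparisons` (tibble `group1`, `group2`, `diff`, `se`,
#'   `q`, `p_adj`, `significant`) and `letters` (named character vector).
#' @export
tukey_hsd <- function(means, mse, n, alpha = 0.05,
                      df_error = sum(rep(n, length.out = length(means))) -
                        length(means)) {
  k <- length(means)
  if (k < 2) stop("need >= 2 groups for Tukey comparisons", call. = FALSE)
  means <- setNames(as.numeric(means),
                    if (is.null(names(means))) paste0("g", seq_len(k))
                    else names(means))
  n <- rep(n, length.out = k)
  pairs <- utils::combn(k, 2)
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt((mse / 2) * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  q <- abs(diff) / se
  p_adj <- ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
  comparisons <- tibble::tibble(
    group1 = names(means)[pairs[1, ]], group2 = names(means)[pairs[2, ]],
    diff = unname(diff), se = unname(se), q = unname(q),
    p_adj = unname(p_adj), significant = unname(p_adj < alpha))
  letters_out <- .compact_letters(names(means), comparisons)
  list(comparisons = comparisons, letters = letters_out)
}

# Insert-and-absorb compact letter display. `comparisons` needs columns
# group1, group2, significant.
.compact_letters <- function(groups, comparisons) {
  cols <- list(setNames(rep(TRUE, length(groups)), groups))
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]
    b <- sig$group2[i]
    for (j in seq_along(cols)) {
      if (isTRUE(cols[[j]][a]) && isTRUE(cols[[j]][b])) {
        col_a <- cols[[j]]; col_a[b] <- FALSE
        col_b <- cols[[j]]; col_b[a] <- FALSE
        cols[[j]] <- col_a
        cols[[length(cols) + 1]] <- col_b
      }
    }
    # absorb columns wholly contained in another
    drop <- rep(FALSE, length(cols))
    for (j in seq_along(cols)) {
      for (m in seq_along(cols)) {
        if (j != m && !drop[j] && !drop[m] &&
            all(cols[[m]][cols[[j]]])) {
          drop[j] <- TRUE
        }
      }
    }
    cols <- cols[!drop]
  }
  lab <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols)) {
    members <- names(cols[[j]])[cols[[j]]]
    lab[members] <- paste0(lab[members], letters[j])
  }
  lab
}
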