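#' Test genes for rare-variant enrichment in phenotype clusters
#'
#' For every panel gene, compares per-individual qualifying-variant counts
#' (or carrier flags) across phenotype clusters with a classic one-way ANOVA
#' (pooled variance), optionally followed by pairwise pooled two-sample
#' t-tests over all cluster pairs. Bonferroni correction is applied over the
#' number of testable genes for the ANOVA family and over testable genes x
#' cluster pairs for the pairwise family; the two families are corrected and
#' reported separately. Genes with zero variance overall are untestable and
#' reported with NA p-values.
#'
#' @param carriers individuals x genes matrix of qualifying-variant counts.
#' @param labels cluster label per individual (aligned with rows).
#' @param alpha significance level for flagging (on Bonferroni-adjusted p).
#' @param use_carrier_flag test the 0/1 carrier indicator instead of counts.
#' @param pairwise also run pairwise cluster t-tests.
#' @return list with `anova` (data.frame: gene, f_stat, p_raw, p_bonferroni,
#'   flagged, testable) and `pairwise` (data.frame: gene, pair, p_raw,
#'   p_bonferroni; NULL when `pairwise = FALSE`).
#' @export
enrichment_scan <- function(carriers, labels, alpha = 0.05,
                            use_carrier_flag = FALSE, pairwise = TRUE) {
  if (length(labels) != nrow(carriers))
    rc_stop("labels must align with carrier-matrix rows")
  f <- factor(labels)
  if (nlevels(f) < 2) rc_stop("need at least 2 non-empty clusters")
  genes <- colnames(carriers)

  one_gene <- function(g) {
    y <- carriers[, g]
    if (use_carrier_flag) y <- as.numeric(y > 0)
    if (stats::var(y) == 0)
      return(list(f_stat = NA_real_, p = NA_real_, testable = FALSE, y = y))
    ft <- stats::oneway.test(y ~ f, var.equal = TRUE)
    list(f_stat = unname(ft$statistic), p = ft$p.value, testable = TRUE,
         y = y)
  }
  fits <- lapply(genes, one_gene)
  n_testable <- sum(vapply(fits, `[[`, logical(1), "testable"))

  anova_df <- data.frame(
    gene = genes,
    f_stat = vapply(fits, `[[`, numeric(1), "f_stat"),
    p_raw = vapply(fits, `[[`, numeric(1), "p"),
    testable = vapply(fits, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE
  )
  anova_df$p_bonferroni <- pmin(1, anova_df$p_raw * n_testable)
  anova_df$flagged <- !is.na(anova_df$p_bonferroni) &
    anova_df$p_bonferroni < alpha

  pw_df <- NULL
  if (pairwise) {
    lev <- levels(f)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    rows <- list()
    for (i in seq_along(genes)) {
      if (!fits[[i]]$testable) next
      y <- fits[[i]]$y
      for (pr in pairs) {
        a <- y[f == pr[1]]; b <- y[f == pr[2]]
        p <- tryCatch(
          stats::t.test(a, b, var.equal = TRUE)$p.value,
          error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          gene = genes[i], pair = paste(pr, collapse = "-"),
          p_raw = p, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      pw_df <- do.call(rbind, rows)
      n_tests <- sum(!is.na(pw_df$p_raw))
      pw_df$p_bonferroni <- pmin(1, pw_df$p_raw * n_tests)
    }
  }
  list(anova = anova_df, pairwise = pw_df, alpha = alpha)
}

#' Distribution of syndromic cases over phenotype clusters
#'
#' Builds the k-cell contingency table of syndromic-case counts per cluster
#' and tests it against the null that syndromic status is independent of
#' cluster membership (expected counts proportional to cluster sizes). A
#' chi-square goodness-of-fit test is used; when any expected count drops
#' below 5 the p-value is computed exactly by enumerating all multinomial
#' allocations of the syndromic cases over clusters and summing the
#' probability of tables at least as extreme (by chi-square statistic).
#'
#' @param labels cluster label per individual.
#' @param syndromic logical flag per individual.
#' @return list with `table` (syndromic counts by cluster), `expected`,
#'   `p_value` (NA with zero syndromic cases) and `method`.
#' @export
syndromic_distribution <- function(labels, syndromic) {
  if (length(labels) != length(syndromic))
    rc_stop("labels and syndromic flags must align")
  f <- factor(labels)
  sizes <- table(f)
  counts <- table(factor(labels[syndromic], levels = levels(f)))
  s <- sum(counts)
  expected <- s * as.numeric(sizes) / length(labels)
  names(expected) <- levels(f)
  if (s == 0)
    return(list(table = counts, expected = expected, p_value = NA_real_,
                method = "none (no syndromic cases)"))
  probs <- as.numeric(sizes) / length(labels)
  chi_obs <- sum((as.numeric(counts) - expected)^2 / expected)
  k <- nlevels(f)
  if (all(expected >= 5)) {
    p <- stats::pchisq(chi_obs, df = k - 1, lower.tail = FALSE)
    method <- "chi-square"
  } else {
    p <- exact_multinomial_tail(s, probs, chi_obs)
    method <- "exact multinomial"
  }
  list(table = counts, expected = expected, p_value = p, method = method)
}

# exact multinomial goodness-of-fit tail: P(chi2(counts) >= chi_obs) for
# counts ~ Multinomial(s, probs); enumerates all compositions of s into k
exact_multinomial_tail <- function(s, probs, chi_obs, tol = 1e-12) {
  k <- length(probs)
  expected <- s * probs
  total <- 0
  rec <- function(cell, remaining, counts) {
    if (cell == k) {
      counts[k] <- remaining
      chi <- sum((counts - expected)^2 / expected)
      if (chi >= chi_obs - tol)
        total <<- total + stats::dmultinom(counts, prob = probs)
      return(invisible())
    }
    for (c in 0:remaining) {
      counts[cell] <- c
      rec(cell + 1, remaining - c, counts)
    }
  }
  if (choose(s + k - 1, k - 1) > 2e6)
    rc_stop("too many multinomial tables to enumerate exactly")
  rec(1, s, numeric(k))
  min(1, total)
}
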