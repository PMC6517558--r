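#' RVIS-weighted rare-variant burden per individual
#'
#' The burden of individual i is `B_i = sum_g v_ig * w_g`, where `v_ig` is
#' the count of qualifying rare variants in gene g and `w_g = 1 -
#' rvis_percentile_g / 100` is the genic-intolerance weight. Siblings are
#' scored separately like any other individual: different rare variants may
#' contribute to each sib's phenotype.
#'
#' @param carriers individuals x genes matrix of qualifying-variant counts.
#' @param panel gene panel covering every column of `carriers`.
#' @return named numeric vector of per-individual burden scores.
#' @export
burden_score <- function(carriers, panel) {
  panel <- as_panel(panel)
  genes <- colnames(carriers)
  missing <- setdiff(genes, panel$gene)
  if (length(missing))
    rc_stop("genes absent from the panel: ", paste(missing, collapse = ", "))
  w <- panel$weight[match(genes, panel$gene)]
  drop(carriers %*% w)
}

#' Exact binomial test for per-gene rare-variant carrier excess
#'
#' Given `k` carriers among `n` unrelated individuals and a reference
#' background probability `p_g` that an individual carries at least one rare
#' variant in the gene, returns the one-sided upper-tail probability
#' `P(X >= k)` for `X ~ Binomial(n, p_g)` — the chance of observing at least
#' as many carriers under the reference carrier frequency.
#'
#' @param k observed carriers (0 <= k <= n).
#' @param n number of unrelated individuals.
#' @param p_g background carrier probability in `[0, 1]`.
#' @return p-value in `(0, 1]` (0 only in the degenerate `p_g = 0, k > 0`
#'   case, which is reported with a warning as a model violation).
#' @examples
#' sorva_test(2, 2, 0.5)  # 0.25
#' @export
sorva_test <- function(k, n, p_g) {
  if (!is_number(k) || !is_number(n) || k < 0 || k > n || k %% 1 != 0)
    rc_stop("k must be an integer with 0 <= k <= n")
  if (!is_number(p_g) || p_g < 0 || p_g > 1)
    rc_stop("p_g must lie in [0, 1]")
  if (k == 0) return(1)
  if (p_g == 0) {
    rc_warn("carriers observed under a zero background probability; ",
            "the binomial model is violated")
    return(0)
  }
  stats::pbinom(k - 1, size = n, prob = p_g, lower.tail = FALSE)
}

#' Scan a panel for genes with a rare-variant carrier excess
#'
#' For every panel gene, counts carrier individuals (at least one qualifying
#' variant) among the unrelated part of the cohort and tests the count
#' against the gene's background carrier probability with [sorva_test()].
#' Sib-pairs are reported descriptively — `s` pairs in which both members
#' carry a qualifying variant in the gene, out of `n_sib` pairs — and are
#' excluded from the p-value, which is computed on unrelated individuals
#' only. Both the carrier count `k` and the total variant count in the gene
#' are reported, since the two can differ when individuals carry several
#' variants.
#'
#' @param carriers individuals x genes matrix of qualifying-variant counts.
#' @param panel gene panel with `background_carrier_prob`.
#' @param families family id per individual (`NA` = unrelated); ids occurring
#'   exactly twice define sib-pairs, anything else is treated as unrelated
#'   with a warning.
#' @param alpha significance level for flagging.
#' @param bonferroni apply Bonferroni correction over the panel before
#'   flagging (default FALSE: raw p-values, one row per gene).
#' @return data.frame with columns `gene`, `k`, `n`, `variant_count`, `s`,
#'   `n_sib`, `p_value` (and `p_bonferroni` if requested), `flagged`.
#' @export
sorva_scan <- function(carriers, panel, families = NULL, alpha = 0.05,
                       bonferroni = FALSE) {
  panel <- as_panel(panel)
  n_ind <- nrow(carriers)
  if (is.null(families)) families <- rep(NA_character_, n_ind)
  if (length(families) != n_ind)
    rc_stop("families must align with carrier-matrix rows")

  fam_tab <- table(families[!is.na(families)])
  odd <- names(fam_tab)[fam_tab != 2]
  if (length(odd)) {
    rc_warn("family id(s) without exactly two members treated as unrelated: ",
            paste(odd, collapse = ", "))
    families[families %in% odd] <- NA_character_
  }
  sib_fams <- names(fam_tab)[fam_tab == 2]
  unrelated <- is.na(families)
  n <- sum(unrelated)
  n_sib <- length(sib_fams)

  res <- lapply(panel$gene, function(g) {
    if (!g %in% colnames(carriers))
      rc_stop("gene missing from carrier matrix: ", g)
    v <- carriers[, g]
    k <- sum(v[unrelated] > 0)
    s <- sum(vapply(sib_fams,
                    function(f) all(v[which(families == f)] > 0),
                    logical(1)))
    p_g <- panel$background_carrier_prob[panel$gene == g]
    data.frame(gene = g, k = k, n = n,
               variant_count = sum(v[unrelated]),
               s = s, n_sib = n_sib,
               p_value = sorva_test(k, n, p_g),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (bonferroni) {
    res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
    res$flagged <- res$p_bonferroni < alpha
  } else {
    res$flagged <- res$p_value < alpha
  }
  res
}

#' Ordinary least-squares regression of y on x
#'
#' Thin wrapper around [stats::lm()] returning the slope, intercept,
#' coefficient of determination and the two-sided slope p-value (t
#' distribution, n - 2 df). Used for burden vs. severity and burden vs.
#' malformation-count correlations.
#'
#' @param x,y numeric vectors of equal length (n >= 3; x not constant).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  if (length(x) != length(y)) rc_stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) rc_stop("regression needs at least 3 complete pairs")
  if (stats::var(x) == 0) rc_stop("x is constant; the slope is unidentifiable")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Two-tailed two-sample t-test p-value
#'
#' Welch's unequal-variance t-test by default; set `var_equal = TRUE` for the
#' pooled-variance Student's t. Used for burden by sex and malformation
#' counts by syndromic status.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal pool the variances.
#' @return two-sided p-value.
#' @export
ttest_two_tailed <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    rc_stop("each group needs at least 2 observations")
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Calibrated severity score lookup
#'
#' Maps an ADOS raw total to the 1-10 calibrated severity scale through a
#' user-supplied lookup table with columns `module`, `age_min`, `age_max`,
#' `raw_min`, `raw_max`, `score`. Raw totals outside the covered range for a
#' (module, age) stratum are clamped to the nearest band with a warning.
#'
#' @param raw_total ADOS raw total score(s).
#' @param age age(s) in years.
#' @param module ADOS module(s).
#' @param table the lookup table data.frame.
#' @return integer severity score(s) in 1..10.
#' @export
calibrated_severity <- function(raw_total, age, module, table) {
  need <- c("module", "age_min", "age_max", "raw_min", "raw_max", "score")
  miss <- setdiff(need, names(table))
  if (length(miss))
    rc_stop("severity table missing columns: ", paste(miss, collapse = ", "))
  n <- max(length(raw_total), length(age), length(module))
  raw_total <- rep_len(raw_total, n)
  age <- rep_len(age, n)
  module <- rep_len(module, n)
  vapply(seq_len(n), function(i) {
    band <- table[table$module == module[i] &
                    table$age_min <= age[i] & age[i] <= table$age_max, ,
                  drop = FALSE]
    if (nrow(band) == 0)
      rc_stop("no severity-table cell for module ", module[i],
              ", age ", age[i])
    hit <- band[band$raw_min <= raw_total[i] &
                  raw_total[i] <= band$raw_max, , drop = FALSE]
    if (nrow(hit) == 0) {
      rc_warn("raw total ", raw_total[i], " outside the covered range for ",
              "module ", module[i], ", age ", age[i], "; clamped")
      if (raw_total[i] < min(band$raw_min)) {
        hit <- band[which.min(band$raw_min), , drop = FALSE]
      } else {
        hit <- band[which.max(band$raw_max), , drop = FALSE]
      }
    }
    as.integer(hit$score[1])
  }, integer(1))
}
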