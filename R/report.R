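#' Diagnostic-yield percentages
#'
#' Total yield is the percentage of the cohort with a syndromic molecular
#' diagnosis; the second figure excludes cases detected by a dedicated
#' screening assay (e.g. Fragile X repeat testing) rather than by
#' sequencing. Display values are rounded half-up to 2 decimals; the
#' full-precision values are returned alongside.
#'
#' @param n_diagnosed diagnosed (syndromic) cases.
#' @param n_screen_detected of those, cases found by screening assays.
#' @param n_total cohort size (> 0).
#' @return list with `total_pct`, `excl_screen_pct` (full precision) and
#'   `total_pct_display`, `excl_screen_pct_display` (2-decimal, half-up).
#' @examples
#' diagnostic_yield(13, 4, 174)  # display values 7.47 and 5.17
#' @export
diagnostic_yield <- function(n_diagnosed, n_screen_detected, n_total) {
  if (!is_number(n_total) || n_total <= 0) rc_stop("n_total must be positive")
  if (n_screen_detected < 0 || n_screen_detected > n_diagnosed ||
      n_diagnosed > n_total)
    rc_stop("need 0 <= n_screen_detected <= n_diagnosed <= n_total")
  total <- 100 * n_diagnosed / n_total
  excl <- 100 * (n_diagnosed - n_screen_detected) / n_total
  list(total_pct = total, excl_screen_pct = excl,
       total_pct_display = round_half_up(total, 2),
       excl_screen_pct_display = round_half_up(excl, 2))
}

#' Summarize a cohort phenotype table
#'
#' Computes the clinical-demographic summary: sex counts and male:female
#' ratio, median age with IQR, sib-pair count (family ids occurring twice),
#' the minor-malformation histogram, and mean malformation counts by
#' syndromic status with a two-tailed Welch t-test p-value.
#'
#' @param phenotypes data.frame with columns `sex` (`male`/`female`),
#'   optional `family`, `age`, `malformations`, `syndromic`.
#' @return list of class `rc_cohort_summary`.
#' @export
summarize_cohort <- function(phenotypes) {
  n_total <- nrow(phenotypes)
  sex <- tolower(substr(as.character(phenotypes$sex), 1, 1))
  n_male <- sum(sex == "m", na.rm = TRUE)
  n_female <- sum(sex == "f", na.rm = TRUE)
  n_missing_sex <- n_total - n_male - n_female
  if (n_missing_sex > 0)
    rc_warn(n_missing_sex, " individual(s) with missing sex excluded from ",
            "the sex ratio")
  out <- list(
    n_total = n_total,
    n_male = n_male,
    n_female = n_female,
    sex_ratio = if (n_female > 0) n_male / n_female else NA_real_,
    median_age = NA_real_, iqr_age = c(NA_real_, NA_real_),
    n_sibpairs = 0L,
    malformation_histogram = NULL,
    mean_malformations = NULL,
    malformation_p = NA_real_
  )
  if (!is.null(phenotypes$age)) {
    out$median_age <- stats::median(phenotypes$age, na.rm = TRUE)
    out$iqr_age <- unname(stats::quantile(phenotypes$age, c(0.25, 0.75),
                                          na.rm = TRUE))
  }
  if (!is.null(phenotypes$family)) {
    fam_tab <- table(phenotypes$family[!is.na(phenotypes$family)])
    out$n_sibpairs <- sum(fam_tab == 2)
  }
  if (!is.null(phenotypes$malformations)) {
    out$malformation_histogram <- table(phenotypes$malformations)
    if (!is.null(phenotypes$syndromic)) {
      syn <- phenotypes$malformations[phenotypes$syndromic]
      non <- phenotypes$malformations[!phenotypes$syndromic]
      out$mean_malformations <- c(syndromic = mean(syn, na.rm = TRUE),
                                  non_syndromic = mean(non, na.rm = TRUE))
      if (length(syn) >= 2 && length(non) >= 2)
        out$malformation_p <- ttest_two_tailed(syn, non)
    }
  }
  structure(out, class = "rc_cohort_summary")
}

#' @exportS3Method base::print
print.rc_cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  n = %d (M/F = %d/%d = %s/1)\n", x$n_total, x$n_male,
              x$n_female,
              ifelse(is.na(x$sex_ratio), "NA",
                     format(round_half_up(x$sex_ratio, 2)))))
  if (!is.na(x$median_age))
    cat(sprintf("  median age = %.1f (IQR %.1f-%.1f)\n", x$median_age,
                x$iqr_age[1], x$iqr_age[2]))
  cat(sprintf("  sib-pairs = %d\n", x$n_sibpairs))
  if (!is.null(x$mean_malformations))
    cat(sprintf("  mean malformations: syndromic %.2f vs non-syndromic %.2f (p = %.3g)\n",
                x$mean_malformations["syndromic"],
                x$mean_malformations["non_syndromic"], x$malformation_p))
  invisible(x)
}
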