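test_that("RVIS weights invert the percentile", {
  expect_identical(rvis_weight(2), 0.98)
  expect_identical(rvis_weight(100), 0)
  expect_identical(rvis_weight(50), 0.5)
  expect_error(rvis_weight(0), "\\(0, 100\\]")
  expect_error(rvis_weight(101), "\\(0, 100\\]")
})

test_that("burden scores are weighted variant counts, linear and order-invariant", {
  panel <- data.frame(gene = c("G1", "G2"),
                      rvis_percentile = c(2, 50),
                      background_carrier_prob = c(0.1, 0.1),
                      chromosome = c("1", "2"))
  cm <- matrix(c(2, 1), nrow = 1, dimnames = list("I1", c("G1", "G2")))
  expect_equal(unname(burden_score(cm, panel)), 2 * 0.98 + 1 * 0.5) # 2.46

  cm0 <- matrix(0L, 3, 2, dimnames = list(paste0("I", 1:3), c("G1", "G2")))
  expect_equal(unname(burden_score(cm0, panel)), c(0, 0, 0))

  cm3 <- matrix(rpois(6, 1), 3, 2,
                dimnames = list(paste0("I", 1:3), c("G1", "G2")))
  expect_equal(burden_score(2 * cm3, panel), 2 * burden_score(cm3, panel))
  # permutation of individuals and of gene columns
  perm <- c(3, 1, 2)
  expect_equal(burden_score(cm3[perm, ], panel), burden_score(cm3, panel)[perm])
  expect_equal(burden_score(cm3[, c("G2", "G1")], panel),
               burden_score(cm3, panel))
  expect_error(burden_score(matrix(0, 1, 1, dimnames = list("I", "GX")),
                            panel), "GX")
})

test_that("carrier-excess test matches closed forms and the enumeration oracle", {
  expect_equal(sorva_test(0, 10, 0.3), 1)
  expect_equal(sorva_test(2, 2, 0.5), 0.25)
  expect_warning(p0 <- sorva_test(3, 10, 0), "model violation|violated")
  expect_equal(p0, 0)
  expect_equal(sorva_test(30, 164, 0.08),
               binom_upper_tail_bruteforce(30, 164, 0.08),
               tolerance = 1e-12)
  expect_error(sorva_test(5, 4, 0.1), "k must")
})

test_that("carrier-excess p-value is strictly decreasing in k and in p_g", {
  for (n in c(10, 50)) {
    ps <- vapply(1:n, sorva_test, numeric(1), n = n, p_g = 0.2)
    expect_true(all(diff(ps) < 0))
  }
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  ps <- vapply(grid, function(p) sorva_test(5, 40, p), numeric(1))
  expect_true(all(diff(ps) > 0))  # larger p_g => larger tail => less excess
})

test_that("panel scan counts carriers, sib-pair sharing, and controls error", {
  # deterministic accounting on a tiny cohort: 4 unrelated + 1 sib-pair
  cm <- matrix(0L, 6, 2, dimnames = list(
    c("U1", "U2", "U3", "U4", "S1", "S2"), c("G1", "G2")))
  cm[c("U1", "U2"), "G1"] <- 1L
  cm[c("S1", "S2"), "G1"] <- 1L
  cm["S1", "G2"] <- 2L
  panel <- data.frame(gene = c("G1", "G2"), rvis_percentile = c(10, 20),
                      background_carrier_prob = c(0.1, 0.1),
                      chromosome = c("1", "2"))
  fams <- c(NA, NA, NA, NA, "F1", "F1")
  res <- sorva_scan(cm, panel, families = fams, alpha = 0.05)
  expect_equal(res$k, c(2, 0))
  expect_equal(res$n, c(4, 4))
  expect_equal(res$s, c(1, 0))
  expect_equal(res$n_sib, c(1, 1))
  expect_equal(res$variant_count, c(2, 0))
  expect_equal(res$p_value[1], sorva_test(2, 4, 0.1))
  expect_false(res$flagged[2])  # zero carriers never flagged

  expect_warning(sorva_scan(cm, panel, families = c(fams[-6], "F9")),
                 "treated as unrelated")
})

test_that("panel scan holds its type-I level and detects planted enrichment", {
  n <- 164; G <- 20; p0 <- 0.5
  panel <- data.frame(gene = paste0("G", 1:G),
                      rvis_percentile = rep(50, G),
                      background_carrier_prob = rep(p0, G),
                      chromosome = rep("1", G))
  set.seed(31)
  flags <- replicate(100, {
    cm <- matrix(rbinom(n * G, 1, p0), n, G,
                 dimnames = list(sprintf("I%03d", 1:n), panel$gene))
    mean(sorva_scan(cm, panel, alpha = 0.05)$flagged)
  })
  # exact achievable level of the discrete test at alpha = 0.05
  k_star <- min(which(pbinom(0:n - 1, n, p0, lower.tail = FALSE) < 0.05)) - 1
  exact_level <- pbinom(k_star - 1, n, p0, lower.tail = FALSE)
  se <- sqrt(exact_level * (1 - exact_level) / (100 * G))
  expect_lt(abs(mean(flags) - exact_level), 4 * se)

  # planted enrichment: multiplier 3 on p_g = 0.05
  set.seed(32)
  hits <- replicate(100, {
    cm <- matrix(rbinom(n * G, 1, 0.05), n, G,
                 dimnames = list(sprintf("I%03d", 1:n), panel$gene))
    cm[, 1] <- rbinom(n, 1, 0.15)
    panel2 <- panel
    panel2$background_carrier_prob <- rep(0.05, G)
    sorva_scan(cm, panel2, alpha = 0.05)$flagged[1]
  })
  expect_gte(mean(hits), 0.8)
})

test_that("regression reproduces the closed-form OLS solution", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  fit <- regress(x, y)
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - sxy / sxx * mean(x),
               tolerance = 1e-12)

  fit2 <- regress(x, 2 * x)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_error(regress(rep(1, 5), y), "constant")
  expect_error(regress(1:2, 1:2), "at least 3")
})

test_that("null regression slope stays within 3 standard errors of zero", {
  set.seed(17)
  x <- rnorm(2000)
  y <- rnorm(2000)
  fit <- regress(x, y)
  se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(fit$slope), 3 * se)
})

test_that("two-tailed t-test: identity, type-I level, and power", {
  a <- c(1, 2, 3, 4)
  expect_equal(ttest_two_tailed(a, a), 1)

  set.seed(23)
  rejections <- replicate(1000,
    ttest_two_tailed(rnorm(50), rnorm(50)) < 0.05)
  expect_lt(abs(mean(rejections) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  set.seed(24)
  power <- mean(replicate(200,
    ttest_two_tailed(rnorm(100, 0), rnorm(100, 1)) < 0.05))
  expect_gte(power, 0.99)
})

test_that("calibrated severity lookup is deterministic, clamped, monotone", {
  tab <- read.delim(toy_file("severity_table_synthetic.tsv"))
  expect_equal(calibrated_severity(21, 6, 3, tab), 9L)
  expect_equal(calibrated_severity(10, 6, 2, tab), 5L)
  expect_warning(lo <- calibrated_severity(-2, 6, 3, tab), "clamped")
  expect_equal(lo, 1L)
  expect_warning(hi <- calibrated_severity(40, 6, 3, tab), "clamped")
  expect_equal(hi, 10L)
  scores <- calibrated_severity(0:28, 6, 3, tab)
  expect_true(all(diff(scores) >= 0))
  expect_error(calibrated_severity(10, 6, 1, tab), "no severity-table cell")
})
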