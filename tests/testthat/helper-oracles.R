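# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# binomial upper tail P(X >= k) by direct pmf summation over choose() terms
binom_upper_tail_bruteforce <- function(k, n, p) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# plug-in mutual information (bits) over the explicit 2x2 joint table
mi_plugin_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x == a & y == b) / n
    pa <- sum(x == a) / n
    pb <- sum(y == b) / n
    if (pab > 0) mi <- mi + pab * log2(pab / (pa * pb))
  }
  mi
}

# empirical binary entropy in bits
entropy_oracle <- function(x) {
  p <- mean(x)
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

toy_file <- function(f) system.file("extdata", f, package = "rarecohort")

load_toy <- function() {
  load_cohort(toy_file("toy_cohort.vcf"), toy_file("toy_annotations.tsv"))
}

toy_panel <- function() read_panel(toy_file("toy_panel.tsv"))

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
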