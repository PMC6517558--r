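#' Gene-intolerance weight from an RVIS percentile
#'
#' Converts a gene's RVIS (residual variation intolerance score) percentile
#' into the burden weight `w = 1 - percentile / 100`, so that the most
#' intolerant genes (lowest percentiles) receive weights close to 1. A gene
#' at the 2nd percentile gets weight 0.98.
#'
#' @param rvis_percentile numeric vector of percentiles in `(0, 100]`.
#' @return numeric vector of weights in `[0, 1)`.
#' @examples
#' rvis_weight(2)    # 0.98
#' rvis_weight(100)  # 0: most tolerant gene contributes nothing
#' @export
rvis_weight <- function(rvis_percentile) {
  if (!is.numeric(rvis_percentile) || length(rvis_percentile) == 0)
    rc_stop("rvis_percentile must be numeric")
  if (any(!is.finite(rvis_percentile)) ||
      any(rvis_percentile <= 0 | rvis_percentile > 100))
    rc_stop("RVIS percentile must lie in (0, 100]")
  1 - rvis_percentile / 100
}

#' Read a gene-panel table
#'
#' The panel TSV must have columns `gene`, `rvis_percentile`,
#' `background_carrier_prob` (the fraction of reference-population individuals
#' carrying at least one rare variant in the gene) and `chromosome`. A
#' `weight` column is added from [rvis_weight()].
#'
#' @param path path to a tab-separated panel file.
#' @return data.frame with one row per panel gene.
#' @export
read_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_panel(panel)
}

#' Validate a gene-panel data.frame
#'
#' @param panel data.frame with columns `gene`, `rvis_percentile`,
#'   `background_carrier_prob`, `chromosome`.
#' @return the validated panel with a `weight` column.
#' @export
as_panel <- function(panel) {
  need <- c("gene", "rvis_percentile", "background_carrier_prob", "chromosome")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    rc_stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$gene))
    rc_stop("panel has duplicated gene symbols")
  p <- panel$background_carrier_prob
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    rc_stop("background_carrier_prob must lie in [0, 1]")
  panel$weight <- rvis_weight(panel$rvis_percentile)
  panel
}

#' Generate a synthetic candidate-gene panel
#'
#' Produces a panel with the shape used throughout the package: 101 genes by
#' default (a typical neurodevelopmental candidate-gene panel size), RVIS
#' percentiles spread over (0, 100], and background carrier probabilities in
#' a range typical of reference-population rare-variant carrier fractions.
#'
#' @param n_genes number of panel genes.
#' @param seed integer random seed.
#' @param carrier_prob_range range the background carrier probabilities are
#'   drawn from, uniformly.
#' @return a panel data.frame (see [as_panel()]).
#' @export
synthetic_panel <- function(n_genes = 101, seed = 1,
                            carrier_prob_range = c(0.01, 0.12)) {
  if (n_genes < 1) rc_stop("n_genes must be >= 1")
  set.seed(seed)
  panel <- data.frame(
    gene = sprintf("GENE%03d", seq_len(n_genes)),
    rvis_percentile = stats::runif(n_genes, 0.5, 100),
    background_carrier_prob = stats::runif(
      n_genes, carrier_prob_range[1], carrier_prob_range[2]),
    chromosome = sample(c(as.character(1:22), "X"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  as_panel(panel)
}
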