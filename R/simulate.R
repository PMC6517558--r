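#' Simulation configuration for a synthetic case-only cohort
#'
#' Bundles and validates everything [simulate_genotypes()] needs. The default
#' cohort shape mirrors a mid-sized case-only gene-panel study: 164 unrelated
#' probands plus 5 sib-pairs (174 individuals) screened over a 101-gene panel.
#'
#' @param n_unrelated number of unrelated individuals (>= 0).
#' @param n_sibpairs number of sib-pairs (>= 0); both sibs are cases.
#' @param panel gene panel (see [as_panel()]).
#' @param enrichment named numeric vector of per-gene multipliers (>= 1)
#'   applied to the background carrier probability; names must be panel genes.
#' @param seed integer random seed; a fixed seed makes every output
#'   (VCF text, tables, matrices) identical across runs.
#' @return a list of class `rc_sim_config`.
#' @export
sim_config <- function(n_unrelated = 164, n_sibpairs = 5,
                       panel = synthetic_panel(), enrichment = NULL,
                       seed = 1) {
  if (!is_number(n_unrelated) || n_unrelated < 0 || n_unrelated %% 1 != 0)
    rc_stop("n_unrelated must be a non-negative integer")
  if (!is_number(n_sibpairs) || n_sibpairs < 0 || n_sibpairs %% 1 != 0)
    rc_stop("n_sibpairs must be a non-negative integer")
  panel <- as_panel(panel)
  mult <- rep(1, nrow(panel))
  names(mult) <- panel$gene
  if (!is.null(enrichment)) {
    if (is.null(names(enrichment)) || !all(names(enrichment) %in% panel$gene))
      rc_stop("enrichment multipliers must be named by panel genes")
    if (any(enrichment < 1)) rc_stop("enrichment multipliers must be >= 1")
    mult[names(enrichment)] <- enrichment
  }
  p_eff <- panel$background_carrier_prob * mult
  if (any(p_eff > 1))
    rc_stop("carrier probability exceeds 1 after enrichment for: ",
            paste(panel$gene[p_eff > 1], collapse = ", "))
  structure(list(n_unrelated = n_unrelated, n_sibpairs = n_sibpairs,
                 panel = panel, p_effective = p_eff, seed = seed),
            class = "rc_sim_config")
}

#' Simulate cohort genotypes over a gene panel
#'
#' Draws, for every unrelated individual and gene, a carrier event with the
#' gene's (possibly enrichment-multiplied) background carrier probability and
#' plants one heterozygous SNV per event at a distinct position. Each
#' sib-pair/gene carrier event simulates one heterozygous carrier parent;
#' each sib inherits the variant independently with probability 1/2, so a
#' "shared" variant (both sibs carry it) arises with probability 1/4 given
#' the event. All simulated variants pass the quality and rarity filters by
#' construction; use the `n_fail_*` arguments to inject records that must be
#' dropped by the filter cascade.
#'
#' @param config an [sim_config()] object.
#' @param dir directory to write `cohort.vcf` (VCF v4.2 with GT and INFO keys
#'   RD/MQ/QD) and `annotations.tsv` into; `NULL` keeps everything in memory.
#' @param n_fail_quality,n_fail_rarity,n_synonymous number of additional
#'   records to inject that fail the quality filter, fail the cohort rarity
#'   cap (3 heterozygous carriers), or are synonymous. Injected records are
#'   not counted in the returned carrier matrix.
#' @return list with elements `carriers` (individuals x genes matrix of
#'   qualifying variant counts), `sample_ids`, `families` (family id per
#'   individual, `NA` for unrelated), `variants`, `annotations`, `vcf_lines`,
#'   and, when `dir` is given, `vcf_path` / `annotation_path`.
#' @export
simulate_genotypes <- function(config, dir = NULL,
                               n_fail_quality = 0, n_fail_rarity = 0,
                               n_synonymous = 0) {
  if (!inherits(config, "rc_sim_config"))
    rc_stop("config must come from sim_config()")
  set.seed(config$seed)
  panel <- config$panel
  n_unrel <- config$n_unrelated
  n_sib <- config$n_sibpairs
  n_total <- n_unrel + 2 * n_sib

  ids <- character(0)
  fams <- character(0)
  if (n_unrel > 0) {
    ids <- sprintf("IND%03d", seq_len(n_unrel))
    fams <- rep(NA_character_, n_unrel)
  }
  if (n_sib > 0) {
    sib_ids <- as.vector(rbind(sprintf("SIB%02d_1", seq_len(n_sib)),
                               sprintf("SIB%02d_2", seq_len(n_sib))))
    ids <- c(ids, sib_ids)
    fams <- c(fams, rep(sprintf("FAM%02d", seq_len(n_sib)), each = 2))
  }

  carriers <- matrix(0L, nrow = n_total, ncol = nrow(panel),
                     dimnames = list(ids, panel$gene))

  # one row per variant record; gt holds the carrier column indices
  var_gene <- integer(0); var_carriers <- list()
  for (g in seq_len(nrow(panel))) {
    p <- config$p_effective[g]
    if (n_unrel > 0) {
      hit <- which(stats::rbinom(n_unrel, 1, p) == 1)
      for (i in hit) {
        var_gene <- c(var_gene, g)
        var_carriers <- c(var_carriers, list(i))
        carriers[i, g] <- carriers[i, g] + 1L
      }
    }
    if (n_sib > 0) {
      ev <- which(stats::rbinom(n_sib, 1, p) == 1)
      for (s in ev) {
        inherit <- stats::rbinom(2, 1, 0.5) == 1
        if (!any(inherit)) next
        cols <- n_unrel + 2 * (s - 1) + which(inherit)
        var_gene <- c(var_gene, g)
        var_carriers <- c(var_carriers, list(cols))
        carriers[cols, g] <- carriers[cols, g] + 1L
      }
    }
  }

  kind <- rep("signal", length(var_gene))
  inject <- function(n, what) {
    if (n > 0 && n_total < ifelse(what == "rarity", 3, 1))
      rc_stop("cohort too small to inject ", what, "-failing records")
    for (j in seq_len(n)) {
      var_gene <<- c(var_gene, 1L)
      var_carriers <<- c(var_carriers,
                         list(if (what == "rarity") 1:3 else 1L))
      kind <<- c(kind, what)
    }
  }
  inject(n_fail_quality, "quality")
  inject(n_fail_rarity, "rarity")
  inject(n_synonymous, "synonymous")

  nv <- length(var_gene)
  consequences <- c("missense", "frameshift", "stop_gained",
                    "canonical_splice", "inframe_indel")
  cons_prob <- c(0.75, 0.08, 0.07, 0.05, 0.05)

  pos_counter <- integer(nrow(panel))
  pos <- integer(nv)
  for (v in seq_len(nv)) {
    g <- var_gene[v]
    pos_counter[g] <- pos_counter[g] + 1L
    pos[v] <- g * 100000L + pos_counter[g]
  }

  variants <- data.frame(
    chrom = panel$chromosome[var_gene],
    pos = pos,
    ref = rep("A", nv), alt = rep("G", nv),
    rd = if (nv) round(stats::runif(nv, 40, 200)) else integer(0),
    mq = if (nv) round(stats::runif(nv, 50, 60), 2) else numeric(0),
    qd = if (nv) round(stats::runif(nv, 5, 30), 2) else numeric(0),
    stringsAsFactors = FALSE
  )
  if (nv) variants$rd[kind == "quality"] <- 5L

  annotations <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene = panel$gene[var_gene],
    transcript = if (nv) paste0("TX_", panel$gene[var_gene])
                 else character(0),
    consequence = if (nv) sample(consequences, nv, TRUE, cons_prob)
                  else character(0),
    maf_1000g_eur = if (nv) round(stats::runif(nv, 0, 0.004), 5)
                    else numeric(0),
    maf_exac = if (nv) round(stats::runif(nv, 0, 0.004), 5) else numeric(0),
    maf_inhouse = if (nv) round(stats::runif(nv, 0, 0.004), 5)
                  else numeric(0),
    cadd_phred = if (nv) round(stats::runif(nv, 0, 40), 2) else numeric(0),
    svm_label = if (nv) sample(c("damaging", "tolerated"), nv, TRUE)
                else character(0),
    clinvar_flag = if (nv) stats::rbinom(nv, 1, 0.02) == 1 else logical(0),
    stringsAsFactors = FALSE
  )
  if (nv) annotations$consequence[kind == "synonymous"] <- "synonymous"

  gt <- matrix("0/0", nrow = nv, ncol = n_total)
  for (v in seq_len(nv)) gt[v, var_carriers[[v]]] <- "0/1"

  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  annotations <- annotations[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(variants) <- rownames(annotations) <- NULL

  vcf_lines <- format_vcf(variants, gt, ids)
  out <- list(carriers = carriers, sample_ids = ids, families = fams,
              variants = variants, annotations = annotations,
              vcf_lines = vcf_lines, panel = panel)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$vcf_path <- file.path(dir, "cohort.vcf")
    out$annotation_path <- file.path(dir, "annotations.tsv")
    writeLines(vcf_lines, out$vcf_path)
    utils::write.table(annotations, out$annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

# render variant table + genotype codes as VCF v4.2 text
format_vcf <- function(variants, gt, sample_ids) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RD,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  if (nrow(variants) == 0) return(header)
  info <- sprintf("RD=%d;MQ=%s;QD=%s", variants$rd,
                  format(variants$mq, trim = TRUE, scientific = FALSE),
                  format(variants$qd, trim = TRUE, scientific = FALSE))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  c(header, body)
}

#' Cluster specification for questionnaire simulation
#'
#' @param sizes per-cluster individual counts.
#' @param feature_probs k x m matrix of Bernoulli probabilities: row c gives
#'   the per-item probability of a positive answer in cluster c.
#' @return list of class `rc_cluster_spec` with `k`, `sizes`, `feature_probs`.
#' @export
cluster_spec <- function(sizes, feature_probs) {
  feature_probs <- as.matrix(feature_probs)
  k <- length(sizes)
  if (k < 1) rc_stop("at least one cluster is required")
  if (any(sizes < 0) || any(sizes %% 1 != 0))
    rc_stop("cluster sizes must be non-negative integers")
  if (nrow(feature_probs) != k)
    rc_stop("feature_probs must have one row per cluster")
  if (any(feature_probs < 0 | feature_probs > 1))
    rc_stop("feature probabilities must lie in [0, 1]")
  structure(list(k = k, sizes = as.integer(sizes),
                 feature_probs = feature_probs),
            class = "rc_cluster_spec")
}

#' Default planted-cluster specification
#'
#' Four phenotype clusters over 149 binary questionnaire items: 30
#' discriminative items (assigned round-robin to clusters; probability
#' `p_high` in the owning cluster, `p_low` elsewhere) against a uniform
#' non-discriminative background of `p_background` — a Bernoulli-mixture
#' caricature of the cluster structure clinical questionnaires are screened
#' for. Item probabilities default to the support `{0.1, 0.9}`: binarized
#' clinical findings are predominantly rare, so background items sit at the
#' rare rate 0.1.
#'
#' @param n cohort size; split as evenly as possible across clusters.
#' @param k number of clusters.
#' @param n_items total questionnaire items.
#' @param n_discriminative number of cluster-informative items.
#' @param p_high,p_low,p_background Bernoulli probabilities.
#' @return an [cluster_spec()] object.
#' @export
default_cluster_spec <- function(n = 174, k = 4, n_items = 149,
                                 n_discriminative = 30,
                                 p_high = 0.9, p_low = 0.1,
                                 p_background = 0.1) {
  if (n_discriminative > n_items)
    rc_stop("n_discriminative cannot exceed n_items")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  probs <- matrix(p_background, nrow = k, ncol = n_items)
  for (j in seq_len(n_discriminative)) {
    owner <- ((j - 1) %% k) + 1
    probs[, j] <- p_low
    probs[owner, j] <- p_high
  }
  cluster_spec(sizes, probs)
}

#' Simulate a binarized clinical questionnaire with planted clusters
#'
#' @param spec an [cluster_spec()] object.
#' @param seed integer random seed.
#' @param ids optional individual ids (length = sum of cluster sizes).
#' @return list with `matrix` (individuals x items, 0/1) and `labels`
#'   (true cluster of each individual, for recovery testing).
#' @export
simulate_questionnaire <- function(spec, seed = 1, ids = NULL) {
  if (!inherits(spec, "rc_cluster_spec"))
    rc_stop("spec must come from cluster_spec()")
  set.seed(seed)
  n <- sum(spec$sizes)
  m <- ncol(spec$feature_probs)
  labels <- rep(seq_len(spec$k), spec$sizes)
  mat <- matrix(0L, nrow = n, ncol = m)
  for (c in seq_len(spec$k)) {
    rows <- which(labels == c)
    if (!length(rows)) next
    mat[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 1,
                    rep(spec$feature_probs[c, ], each = length(rows))),
      nrow = length(rows))
  }
  if (is.null(ids)) ids <- sprintf("IND%03d", seq_len(n))
  if (length(ids) != n) rc_stop("ids must match total cluster size")
  dimnames(mat) <- list(ids, sprintf("Q%03d", seq_len(m)))
  list(matrix = mat, labels = labels)
}

#' Simulate phenotypes linked to a rare-variant burden
#'
#' ADOS raw totals follow `intercept + slope * burden + N(0, noise_sd)`;
#' minor-malformation counts are Poisson; sex is Bernoulli with a default
#' male fraction of 129/174 (the ~2.9:1 male:female ratio typical of ASD
#' cohorts); a syndromic flag is Bernoulli with default rate 13/174.
#'
#' @param burden numeric per-individual burden vector (named or not).
#' @param intercept,slope linear link of ADOS raw total on burden.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param male_prob probability an individual is male.
#' @param malformation_mean Poisson mean of minor-malformation counts.
#' @param syndromic_rate probability of the syndromic flag.
#' @param families optional family-id vector aligned with `burden`.
#' @param seed integer random seed.
#' @return data.frame with columns `individual`, `family`, `sex`, `age`,
#'   `ados_raw`, `malformations`, `syndromic`.
#' @export
simulate_phenotypes <- function(burden, intercept = 10, slope = 0,
                                noise_sd = 3, male_prob = 129 / 174,
                                malformation_mean = 2,
                                syndromic_rate = 13 / 174,
                                families = NULL, seed = 1) {
  if (!is_number(noise_sd) || noise_sd < 0)
    rc_stop("noise_sd must be a non-negative number")
  set.seed(seed)
  n <- length(burden)
  ids <- names(burden)
  if (is.null(ids)) ids <- sprintf("IND%03d", seq_len(n))
  if (is.null(families)) families <- rep(NA_character_, n)
  data.frame(
    individual = ids,
    family = families,
    sex = ifelse(stats::rbinom(n, 1, male_prob) == 1, "male", "female"),
    age = round(stats::runif(n, 2, 18), 1),
    ados_raw = intercept + slope * as.numeric(burden) +
      stats::rnorm(n, 0, noise_sd),
    malformations = stats::rpois(n, malformation_mean),
    syndromic = stats::rbinom(n, 1, syndromic_rate) == 1,
    stringsAsFactors = FALSE
  )
}
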