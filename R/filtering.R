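#' Load a multi-sample VCF and its annotation table
#'
#' Parses a VCF v4.2 (GT genotypes; per-site INFO keys RD, MQ, QD) and joins
#' it, by chrom/pos/ref/alt, to a variant annotation TSV with columns
#' `chrom, pos, ref, alt, gene, transcript, consequence, maf_1000g_eur,
#' maf_exac, maf_inhouse, cadd_phred, svm_label, clinvar_flag`. Multi-allelic
#' records are decomposed into bi-allelic entries before joining, because all
#' downstream filter rules are per-allele.
#'
#' @param vcf_path path to the VCF.
#' @param annotation_path path to the annotation TSV.
#' @return list of class `rc_cohort` with `variants` (annotated data.frame),
#'   `genotypes` (variants x individuals matrix with entries in
#'   `hom_ref/het/hom_alt/hemi/missing`) and `sample_ids`.
#' @export
load_cohort <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) rc_stop("VCF has no GT genotypes")
  gt_raw <- as.matrix(gt_raw)
  sample_ids <- colnames(gt_raw)

  rd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "RD")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD")))

  # decompose multi-allelic sites: one row per ALT allele
  rows <- integer(0); allele <- integer(0); alts <- character(0)
  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  for (i in seq_along(alt_split)) {
    k <- length(alt_split[[i]])
    rows <- c(rows, rep(i, k))
    allele <- c(allele, seq_len(k))
    alts <- c(alts, alt_split[[i]])
  }

  variants <- data.frame(
    chrom = fix$CHROM[rows],
    pos = as.integer(fix$POS[rows]),
    ref = fix$REF[rows],
    alt = alts,
    rd = rd[rows], mq = mq[rows], qd = qd[rows],
    stringsAsFactors = FALSE
  )

  genotypes <- matrix("hom_ref", nrow = length(rows), ncol = ncol(gt_raw),
                      dimnames = list(NULL, sample_ids))
  for (j in seq_along(rows)) {
    genotypes[j, ] <- classify_gt(gt_raw[rows[j], ], allele[j])
  }

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
            "maf_1000g_eur", "maf_exac", "maf_inhouse", "cadd_phred",
            "svm_label", "clinvar_flag")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    rc_stop("annotation table is missing columns: ",
            paste(miss, collapse = ", "))
  ann$clinvar_flag <- as.logical(ann$clinvar_flag)
  ann$chrom <- as.character(ann$chrom)

  key_v <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  key_a <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  idx <- match(key_v, key_a)
  if (anyNA(idx)) {
    rc_warn(sum(is.na(idx)), " VCF record(s) lack an annotation row",
            " and are dropped")
    keep <- !is.na(idx)
    variants <- variants[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  extra <- setdiff(need, c("chrom", "pos", "ref", "alt"))
  variants[extra] <- ann[idx, extra]
  if ("canonical" %in% names(ann)) variants$canonical <- ann$canonical[idx]
  rownames(variants) <- NULL

  structure(list(variants = variants, genotypes = genotypes,
                 sample_ids = sample_ids),
            class = "rc_cohort")
}

# classify one VCF GT string vector relative to ALT allele index `allele`
classify_gt <- function(gt, allele) {
  a <- as.character(allele)
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return("missing")
    hits <- sum(parts == a)
    if (length(parts) == 1L) {
      if (hits == 1L) "hemi" else "hom_ref"
    } else if (hits >= 2L) {
      "hom_alt"
    } else if (hits == 1L) {
      "het"
    } else {
      "hom_ref"
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Variant quality filter
#'
#' A site passes when read depth > 10, mapping quality > 40 and
#' quality-by-depth > 2, all strict. Sites with any missing quality field
#' are rejected with a warning.
#'
#' @param rd,mq,qd numeric vectors of read depth, mapping quality and
#'   quality-by-depth.
#' @return logical vector.
#' @export
quality_pass <- function(rd, mq, qd) {
  res <- rd > 10 & mq > 40 & qd > 2
  if (anyNA(res)) {
    rc_warn(sum(is.na(res)),
            " variant(s) rejected for missing quality fields")
    res[is.na(res)] <- FALSE
  }
  res
}

#' Cohort rarity filter
#'
#' A variant is rare when it is carried by at most `hom_cap` homozygous (or
#' hemizygous) individuals AND at most `het_cap` heterozygous individuals in
#' the cohort, and every available reference minor allele frequency
#' (1000 Genomes European, ExAC, in-house) is strictly below `maf_cap`.
#' Missing MAFs pass: absence from reference databases is evidence of rarity,
#' not against it.
#'
#' @param n_hom,n_het per-variant counts of homozygous/hemizygous and
#'   heterozygous carriers in the cohort.
#' @param maf_1000g_eur,maf_exac,maf_inhouse reference MAFs (NA allowed).
#' @param hom_cap,het_cap,maf_cap filter thresholds; defaults follow the
#'   "at most one homozygous or two heterozygous carriers, MAF < 5%" rule.
#' @return logical vector.
#' @export
is_rare <- function(n_hom, n_het, maf_1000g_eur = NA, maf_exac = NA,
                    maf_inhouse = NA, hom_cap = 1, het_cap = 2,
                    maf_cap = 0.05) {
  maf_ok <- function(m) is.na(m) | m < maf_cap
  n_hom <= hom_cap & n_het <= het_cap &
    maf_ok(maf_1000g_eur) & maf_ok(maf_exac) & maf_ok(maf_inhouse)
}

#' Predicted-effect class of a variant
#'
#' Loss-of-function (`lof`): frameshift, stop-gained or canonical splice-site.
#' `damaging_missense`: missense with CADD phred >= 20 OR a damaging
#' meta-SVM label. Everything else is `other`.
#'
#' @param consequence character vector of consequence terms.
#' @param cadd_phred numeric CADD phred scores (NA allowed).
#' @param svm_label character meta-SVM labels (`damaging`/`tolerated`/NA).
#' @param cadd_cutoff CADD threshold for damaging missense (default 20).
#' @return character vector in `{lof, damaging_missense, other}`.
#' @export
effect_class <- function(consequence, cadd_phred = NA, svm_label = NA,
                         cadd_cutoff = 20) {
  lof_terms <- c("frameshift", "stop_gained", "canonical_splice")
  out <- rep("other", length(consequence))
  out[consequence %in% lof_terms] <- "lof"
  dm <- consequence == "missense" &
    ((!is.na(cadd_phred) & cadd_phred >= cadd_cutoff) |
       (!is.na(svm_label) & svm_label == "damaging"))
  out[dm] <- "damaging_missense"
  out
}

#' Apply the quality/rarity/effect filter cascade
#'
#' Filters a loaded cohort down to qualifying rare variants under one of
#' three modes and tallies the per-individual, per-gene carrier matrix:
#' \describe{
#'   \item{rare_all}{quality-passing, canonical-transcript, cohort-rare,
#'     non-synonymous (missense, LoF or in-frame indel) variants.}
#'   \item{rare_predicted_damaging}{additionally requires
#'     [effect_class()] in `{lof, damaging_missense}`.}
#'   \item{known_pathogenic}{quality-passing, canonical variants with the
#'     ClinVar/HGMD pathogenicity flag, regardless of rarity or prediction.}
#' }
#' Variants annotating genes outside the panel are excluded (count reported
#' in the audit log). When an annotation table carries a logical `canonical`
#' column, only canonical-transcript rows are kept; otherwise every row is
#' treated as the canonical transcript.
#'
#' @param cohort an `rc_cohort` from [load_cohort()].
#' @param panel gene panel (see [as_panel()]).
#' @param mode one of `rare_all`, `rare_predicted_damaging`,
#'   `known_pathogenic`.
#' @return list with `variants` (qualifying annotated variants, with an
#'   `effect_class` column), `carriers` (individuals x panel-genes integer
#'   matrix of qualifying-variant counts, columns in panel order) and `log`
#'   (named vector of record counts surviving each cascade stage).
#' @export
filter_cascade <- function(cohort, panel,
                           mode = c("rare_all", "rare_predicted_damaging",
                                    "known_pathogenic")) {
  mode <- match.arg(mode)
  if (!inherits(cohort, "rc_cohort"))
    rc_stop("cohort must come from load_cohort()")
  panel <- as_panel(panel)
  v <- cohort$variants
  gt <- cohort$genotypes
  log <- c(input = nrow(v))

  keep <- v$gene %in% panel$gene
  if (any(!keep))
    message(sum(!keep), " variant(s) annotate genes outside the panel; ",
            "excluded")
  v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
  log["in_panel"] <- nrow(v)

  if ("canonical" %in% names(v)) {
    keep <- !is.na(v$canonical) & v$canonical
    v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
  }
  log["canonical"] <- nrow(v)

  keep <- quality_pass(v$rd, v$mq, v$qd)
  v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
  log["quality"] <- nrow(v)

  if (mode == "known_pathogenic") {
    keep <- !is.na(v$clinvar_flag) & v$clinvar_flag
    v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
    log["clinvar"] <- nrow(v)
  } else {
    n_hom <- rowSums(gt == "hom_alt" | gt == "hemi")
    n_het <- rowSums(gt == "het")
    keep <- is_rare(n_hom, n_het, v$maf_1000g_eur, v$maf_exac, v$maf_inhouse)
    v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
    log["rare"] <- nrow(v)

    nonsyn <- c("missense", "frameshift", "stop_gained", "canonical_splice",
                "inframe_indel")
    keep <- v$consequence %in% nonsyn
    v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
    log["non_synonymous"] <- nrow(v)

    if (mode == "rare_predicted_damaging") {
      ec <- effect_class(v$consequence, v$cadd_phred, v$svm_label)
      keep <- ec %in% c("lof", "damaging_missense")
      v <- v[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
      log["predicted_damaging"] <- nrow(v)
    }
  }
  v$effect_class <- effect_class(v$consequence, v$cadd_phred, v$svm_label)
  rownames(v) <- NULL

  carriers <- carrier_matrix(v, gt, cohort$sample_ids, panel)
  list(variants = v, carriers = carriers, log = log, mode = mode)
}

#' Tally qualifying variants per individual per gene
#'
#' Each variant contributes one count to every individual carrying the
#' alternate allele (het, hom_alt or hemi). Columns follow panel order; panel
#' genes without qualifying variants get zero columns.
#'
#' @param variants qualifying annotated variants (with a `gene` column).
#' @param genotypes matching variants x individuals genotype-class matrix.
#' @param sample_ids individual ids (column order of `genotypes`).
#' @param panel gene panel.
#' @return individuals x genes integer matrix.
#' @export
carrier_matrix <- function(variants, genotypes, sample_ids, panel) {
  panel <- as_panel(panel)
  cm <- matrix(0L, nrow = length(sample_ids), ncol = nrow(panel),
               dimnames = list(sample_ids, panel$gene))
  if (nrow(variants) == 0) return(cm)
  carried <- genotypes == "het" | genotypes == "hom_alt" | genotypes == "hemi"
  for (j in seq_len(nrow(variants))) {
    g <- variants$gene[j]
    cm[carried[j, ], g] <- cm[carried[j, ], g] + 1L
  }
  cm
}

#' Write / read a carrier matrix as CSV
#'
#' Individuals are rows (first column `individual`), genes are columns.
#'
#' @param carriers individuals x genes matrix.
#' @param path output path.
#' @return `read_carrier_matrix` returns the integer matrix with dimnames.
#' @export
write_carrier_matrix <- function(carriers, path) {
  df <- data.frame(individual = rownames(carriers), carriers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_carrier_matrix
#' @export
read_carrier_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$individual
  m
}
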