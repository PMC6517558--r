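#' Binarize a raw clinical questionnaire table
#'
#' Applies one rule per item: `binary` items are passed through (values must
#' already be 0/1), `threshold` items become 1 when the count is at or above
#' the rule's `threshold`, and `presence` items become 1 when the value lies
#' in the rule's `positive` set. Missing values stay missing.
#'
#' @param raw data.frame of raw responses (individuals x items).
#' @param rules named list (one entry per column of `raw`) of rules, each a
#'   list with `type` in `binary/threshold/presence` and, as needed,
#'   `threshold` or `positive`.
#' @return numeric 0/1 matrix with NAs preserved.
#' @export
binarize <- function(raw, rules) {
  miss <- setdiff(names(raw), names(rules))
  if (length(miss))
    rc_stop("no binarization rule for item(s): ", paste(miss, collapse = ", "))
  out <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(rownames(raw), names(raw)))
  for (item in names(raw)) {
    rule <- rules[[item]]
    x <- raw[[item]]
    out[, item] <- switch(
      rule$type,
      binary = {
        if (!all(x %in% c(0, 1, NA)))
          rc_stop("item ", item, " declared binary but has other values")
        as.numeric(x)
      },
      threshold = as.numeric(x >= rule$threshold),
      presence = ifelse(is.na(x), NA_real_,
                        as.numeric(x %in% rule$positive)),
      rc_stop("unknown rule type for item ", item, ": ", rule$type)
    )
  }
  out
}

#' Plug-in mutual information between two binary vectors
#'
#' `MI = sum_ab p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the empirical 2x2
#' joint distribution, with `0 * log 0 = 0`. Missing entries are dropped
#' pairwise. For identical vectors this equals the empirical entropy, so the
#' diagonal of the similarity matrix carries each individual's response
#' entropy.
#'
#' @param x,y binary (0/1, NA allowed) vectors of equal length.
#' @param base logarithm base: 2 for bits (default), `exp(1)` for nats.
#' @return non-negative mutual information.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y)) rc_stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2)
    rc_stop("mutual information needs at least 2 complete pairs")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  joint <- table(factor(x, levels = c(0, 1)),
                 factor(y, levels = c(0, 1))) / n
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    p <- joint[a, b]
    if (p > 0) mi <- mi + p * log(p / (px[a] * py[b]), base = base)
  }
  max(0, unname(mi))
}

#' Pairwise mutual-information similarity kernel
#'
#' Computes the individuals x individuals matrix of pairwise plug-in mutual
#' information over binarized questionnaire rows — the kernel treated as the
#' sample similarity matrix for spectral clustering and kernel PCA.
#' Individuals with more than `max_missing` missing responses are excluded
#' (their ids are reported in a warning). With complete data the computation
#' is vectorized through joint-count cross-products; the result is identical
#' to calling [mutual_information()] per pair.
#'
#' @param Q binary matrix (individuals x items; 0/1 with NA allowed).
#' @param base logarithm base (2 = bits).
#' @param max_missing maximum tolerated fraction of missing items.
#' @return symmetric non-negative matrix; the diagonal holds each
#'   individual's response entropy.
#' @export
similarity_matrix <- function(Q, base = 2, max_missing = 0.5) {
  Q <- as.matrix(Q)
  if (nrow(Q) < 2) rc_stop("need at least 2 individuals")
  frac_na <- rowMeans(is.na(Q))
  drop <- frac_na > max_missing
  if (any(drop)) {
    rc_warn("excluding individual(s) with > ", max_missing * 100,
            "% missing responses: ",
            paste(rownames(Q)[drop], collapse = ", "))
    Q <- Q[!drop, , drop = FALSE]
    if (nrow(Q) < 2) rc_stop("fewer than 2 individuals remain")
  }
  n <- nrow(Q); m <- ncol(Q)
  if (anyNA(Q)) {
    S <- matrix(0, n, n, dimnames = list(rownames(Q), rownames(Q)))
    for (i in seq_len(n)) for (j in i:n) {
      S[i, j] <- S[j, i] <- mutual_information(Q[i, ], Q[j, ], base = base)
    }
    return(S)
  }
  # complete data: joint 2x2 counts for all pairs at once
  n11 <- Q %*% t(Q)
  r1 <- rowSums(Q)
  n10 <- r1 - n11          # x=1, y=0
  n01 <- t(n10)            # x=0, y=1
  n00 <- m - n11 - n10 - n01
  plogp <- function(p, q) ifelse(p > 0, p * log(p / q, base = base), 0)
  p1 <- r1 / m
  px1 <- matrix(p1, n, n); py1 <- t(px1)
  px0 <- 1 - px1; py0 <- 1 - py1
  S <- plogp(n11 / m, px1 * py1) + plogp(n10 / m, px1 * py0) +
    plogp(n01 / m, px0 * py1) + plogp(n00 / m, px0 * py0)
  S <- pmax(S, 0)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(Q), rownames(Q))
  S
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized-Laplacian (Ng–Jordan–Weiss) spectral clustering: zero the
#' affinity diagonal (the reference algorithm defines `A_ii = 0`; the
#' similarity matrix's diagonal carries each individual's entropy, which is
#' self-similarity, not affinity), form `D^(-1/2) A D^(-1/2)`, take the top-k
#' eigenvectors, normalize rows to unit length, and run k-means (50 restarts,
#' fixed seed) on the embedded rows. Four clusters is the default, in line
#' with the low number of phenotype subgroups expected in ASD cohorts.
#'
#' @param S symmetric non-negative similarity matrix.
#' @param k number of clusters.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return integer vector of cluster labels in 1..k, named by individuals.
#' @export
spectral_cluster <- function(S, k = 4, seed = 1, nstart = 50) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (k < 1 || k > n) rc_stop("k must lie in 1..n")
  if (max(abs(S - t(S))) > 1e-8) rc_stop("S must be symmetric")
  if (min(S) < -1e-12) rc_stop("S must be non-negative")

  diag(S) <- 0
  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected"))
  if (comps$no > k)
    rc_stop("similarity graph has ", comps$no, " connected components but ",
            "k = ", k, "; reduce k or check questionnaire connectivity")

  d <- rowSums(S)
  d[d <= 0] <- min(d[d > 0])  # guard isolated-but-connected degenerate rows
  Dinv <- 1 / sqrt(d)
  M <- S * outer(Dinv, Dinv)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  names(labels) <- rownames(S)
  labels
}

#' Kernel PCA embedding of a similarity matrix
#'
#' Double-centers the kernel (row, column and grand means removed), takes the
#' top-d eigenpairs, and scales each eigenvector by the square root of its
#' eigenvalue. Components with non-positive eigenvalues — the
#' mutual-information matrix need not be positive semi-definite — are
#' discarded (a message reports how many were dropped among the top d) and
#' replaced by zero coordinates. The sign of each component is fixed by
#' making its largest-magnitude loading positive, so embeddings are
#' deterministic.
#'
#' @param S symmetric similarity matrix.
#' @param d embedding dimension (default 3, for visualization).
#' @return individuals x d coordinate matrix.
#' @export
kernel_pca <- function(S, d = 3) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (d > n - 1) rc_stop("d must be at most n - 1")
  if (max(abs(S - t(S))) > 1e-8) rc_stop("S must be symmetric")
  rm_ <- rowMeans(S); gm <- mean(S)
  K <- S - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  vals <- eig$values[seq_len(d)]
  tol <- 1e-10 * max(abs(eig$values), 1)
  emb <- matrix(0, n, d, dimnames = list(rownames(S), paste0("PC", 1:d)))
  dropped <- sum(vals <= tol)
  if (dropped == d) rc_warn("kernel has no positive-variance component; ",
                            "returning a zero embedding")
  else if (dropped > 0) message(dropped, " of the top ", d,
                                " kernel components had non-positive ",
                                "eigenvalues and were dropped")
  for (j in seq_len(d)) {
    if (vals[j] <= tol) next
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    emb[, j] <- v * sqrt(vals[j])
  }
  emb
}

#' Per-cluster feature frequencies and top features
#'
#' For every cluster, the relative frequency of a positive answer to each
#' item (missing answers excluded from the denominator) and the `top` most
#' frequent items, ties broken lexicographically by item label. Top-feature
#' lists of different clusters may overlap.
#'
#' @param Q binary questionnaire matrix (individuals x items).
#' @param labels cluster label per individual.
#' @param top number of top features per cluster.
#' @return list with `profile` (clusters x items frequency matrix; NA rows
#'   for empty clusters) and `top_features` (named list of character
#'   vectors).
#' @export
characterize_clusters <- function(Q, labels, top = 10) {
  Q <- as.matrix(Q)
  if (length(labels) != nrow(Q))
    rc_stop("labels must align with questionnaire rows")
  items <- colnames(Q)
  if (is.null(items)) items <- paste0("Q", seq_len(ncol(Q)))
  ks <- sort(unique(labels))
  profile <- matrix(NA_real_, nrow = length(ks), ncol = ncol(Q),
                    dimnames = list(paste0("cluster", ks), items))
  top_features <- vector("list", length(ks))
  names(top_features) <- paste0("cluster", ks)
  for (i in seq_along(ks)) {
    rows <- which(labels == ks[i])
    if (!length(rows)) next
    freq <- colMeans(Q[rows, , drop = FALSE], na.rm = TRUE)
    profile[i, ] <- freq
    ord <- order(-freq, items)
    top_features[[i]] <- items[ord[seq_len(min(top, length(items)))]]
  }
  list(profile = profile, top_features = top_features)
}
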