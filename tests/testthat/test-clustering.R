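test_that("binarization rules cover binary, threshold and presence items", {
  raw <- data.frame(
    already = c(0, 1, NA, 1),
    count = c(0, 1, 3, NA),
    category = c("none", "mild", "severe", NA),
    stringsAsFactors = FALSE
  )
  rules <- list(
    already = list(type = "binary"),
    count = list(type = "threshold", threshold = 1),
    category = list(type = "presence", positive = c("mild", "severe"))
  )
  expected <- matrix(c(0, 1, NA, 1,
                       0, 1, 1, NA,
                       0, 1, 1, NA), ncol = 3,
                     dimnames = list(NULL, c("already", "count", "category")))
  expect_equal(unname(binarize(raw, rules)), unname(expected))
  expect_error(binarize(raw, rules[1:2]), "category")
  expect_error(binarize(data.frame(already = c(0, 2)), rules[1]),
               "declared binary")
})

test_that("mutual information matches closed forms and the plug-in oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  x <- c(0, 0, 1, 1); y <- c(0, 0, 0, 1)
  expect_equal(mutual_information(x, y), mi_plugin_oracle(x, y),
               tolerance = 1e-12)
  expect_equal(mutual_information(x, y), 0.3112781, tolerance = 1e-6)
  # nats option
  expect_equal(mutual_information(x, y, base = exp(1)),
               mi_plugin_oracle(x, y) * log(2), tolerance = 1e-12)
  expect_error(mutual_information(c(0, NA), c(NA, 1)), "complete pairs")
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(5)
  for (i in 1:50) {
    x <- rbinom(20, 1, runif(1, 0.1, 0.9))
    y <- rbinom(20, 1, runif(1, 0.1, 0.9))
    mi <- mutual_information(x, y)
    expect_identical(mi, mutual_information(y, x))
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy_oracle(x), entropy_oracle(y)) + 1e-12)
  }
})

test_that("similarity matrix equals element-wise oracle recomputation", {
  set.seed(8)
  Q <- matrix(rbinom(120, 1, 0.4), nrow = 10, ncol = 12,
              dimnames = list(paste0("I", 1:10), paste0("Q", 1:12)))
  S <- similarity_matrix(Q)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(S[i, j], mi_plugin_oracle(Q[i, ], Q[j, ]),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(S - t(S))), 1e-12)
  # diagonal carries the response entropy
  expect_equal(unname(diag(S)),
               unname(apply(Q, 1, entropy_oracle)), tolerance = 1e-12)
})

test_that("similarity handles identical, constant and missing-heavy rows", {
  Q <- rbind(a = c(0, 1, 0, 1, 1, 0),
             b = c(0, 1, 0, 1, 1, 0),
             c = c(1, 1, 1, 1, 1, 1),
             d = c(1, 0, 1, 0, 0, 1))
  S <- similarity_matrix(Q)
  expect_equal(S["a", "b"], S["a", "a"])
  expect_equal(S["a", "b"], S["b", "b"])
  expect_true(all(S["c", ] == 0))  # constant vector: zero entropy

  Qna <- Q
  Qna["d", 1:4] <- NA
  expect_warning(S2 <- similarity_matrix(Qna), "missing responses")
  expect_equal(rownames(S2), c("a", "b", "c"))
  # pairwise-complete path agrees with the scalar implementation
  Qna2 <- Q
  Qna2["a", 1] <- NA
  S3 <- similarity_matrix(Qna2)
  expect_equal(S3["a", "d"], mutual_information(Qna2["a", ], Qna2["d", ]))
})

test_that("spectral clustering separates an exact block-diagonal kernel", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 1
  S[5:8, 5:8] <- 1
  labels <- spectral_cluster(S, k = 2, seed = 3)
  expect_equal(length(unique(labels[1:4])), 1)
  expect_equal(length(unique(labels[5:8])), 1)
  expect_false(labels[1] == labels[5])
})

test_that("spectral labels are equivariant under permutation of individuals", {
  spec <- default_cluster_spec(n = 60, k = 3, n_items = 40,
                               n_discriminative = 15)
  q <- simulate_questionnaire(spec, seed = 12)
  S <- similarity_matrix(q$matrix)
  lab <- spectral_cluster(S, k = 3, seed = 5)
  set.seed(77)
  perm <- sample(nrow(S))
  lab_p <- spectral_cluster(S[perm, perm], k = 3, seed = 5)
  expect_equal(ari(lab_p, lab[perm]), 1)
})

test_that("spectral clustering errors on a graph with too many components", {
  S <- diag(3) * 1.0
  expect_error(spectral_cluster(S, k = 2), "components")
})

test_that("planted Bernoulli-mixture clusters are recovered", {
  spec <- default_cluster_spec(n = 80, k = 4, n_items = 60,
                               n_discriminative = 20)
  q <- simulate_questionnaire(spec, seed = 9)
  S <- similarity_matrix(q$matrix)
  labels <- spectral_cluster(S, k = 4, seed = 9)
  expect_gte(ari(labels, q$labels), 0.9)
})

test_that("spectral clustering with a fixed seed is deterministic", {
  spec <- default_cluster_spec(n = 40, k = 2, n_items = 30,
                               n_discriminative = 10)
  q <- simulate_questionnaire(spec, seed = 3)
  S <- similarity_matrix(q$matrix)
  expect_identical(spectral_cluster(S, k = 2, seed = 4),
                   spectral_cluster(S, k = 2, seed = 4))
})

test_that("kernel PCA centers the kernel, maps duplicates together, splits blocks", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 1
  S[5:8, 5:8] <- 1
  n <- 8
  rm_ <- rowMeans(S)
  K <- S - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(S)
  expect_lt(max(abs(rowSums(K))), 1e-10)

  emb <- kernel_pca(S, d = 3)
  expect_equal(emb[1, ], emb[2, ], tolerance = 1e-10)  # identical rows
  expect_true(min(emb[1:4, 1]) > max(emb[5:8, 1]) ||
                min(emb[5:8, 1]) > max(emb[1:4, 1]))

  expect_warning(z <- kernel_pca(matrix(1, 5, 5), d = 3), "zero embedding")
  expect_true(all(z == 0))
  expect_error(kernel_pca(S, d = 8), "at most")
})

test_that("cluster characterization reports frequencies and top features", {
  Q <- rbind(
    matrix(rep(c(1, 1, 0, 0), each = 3), nrow = 3),
    matrix(rep(c(0, 0, 1, 1), each = 3), nrow = 3)
  )
  colnames(Q) <- c("Qa", "Qb", "Qc", "Qd")
  labels <- rep(1:2, each = 3)
  res <- characterize_clusters(Q, labels, top = 2)
  expect_equal(unname(res$profile["cluster1", ]), c(1, 1, 0, 0))
  expect_equal(res$top_features$cluster1, c("Qa", "Qb"))
  expect_equal(res$top_features$cluster2, c("Qc", "Qd"))

  # overlap across clusters is allowed: shared always-on item
  Q2 <- cbind(Q, Qe = 1)
  res2 <- characterize_clusters(Q2, labels, top = 3)
  both <- intersect(res2$top_features$cluster1, res2$top_features$cluster2)
  expect_true("Qe" %in% both)

  # planted high-probability items surface as top features
  spec <- default_cluster_spec(n = 80, k = 4, n_items = 40,
                               n_discriminative = 8, p_background = 0.2)
  q <- simulate_questionnaire(spec, seed = 14)
  prof <- characterize_clusters(q$matrix, q$labels, top = 2)
  expect_setequal(prof$top_features$cluster1, c("Q001", "Q005"))
})
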