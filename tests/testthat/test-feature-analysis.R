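# Feature extraction, PCA projection, and the tie-aware leave-one-out
# k-NN accuracy curve.

test_that("feature extraction yields one deterministic 512-vector per frame", {
  w <- init_cnn_weights(build_model(c(16, 16, 3)), seed = 2)
  set.seed(6)
  x <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
  x[, , , 5] <- x[, , , 1] # duplicated frame
  fm <- extract_features(w, x, labels = c("a", "b", "a", "b", "a"),
                         subject_ids = 1:5)
  expect_equal(nrow(fm$features), 5)
  expect_equal(ncol(fm$features), 512)
  expect_equal(fm$features[5, ], fm$features[1, ], tolerance = 1e-12)
  lg <- extract_features(w, x, layer = "logits")
  expect_equal(ncol(lg$features), 2)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  fm2 <- read_features_csv(path)
  expect_equal(unname(fm2$features), unname(fm$features), tolerance = 1e-6)
  expect_equal(fm2$labels, fm$labels)
  unlink(path)
})

test_that("PCA projection matches an explicit covariance eigendecomposition", {
  set.seed(19)
  X <- matrix(rnorm(100), 20, 5)
  pr <- pca_project(X)
  expect_identical(dim(pr$components), c(5L, 3L))
  expect_identical(dim(pr$projected), c(20L, 3L))
  # orthonormal components, descending eigenvalues
  expect_lt(max(abs(crossprod(pr$components) - diag(3))), 1e-10)
  expect_true(all(diff(pr$eigenvalues) <= 1e-12))
  # oracle: eigen() of the centered covariance, compared up to sign
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(pr$eigenvalues, ev$values[1:3], tolerance = 1e-8)
  for (k in 1:3) {
    dot <- abs(sum(pr$components[, k] * ev$vectors[, k]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  # planar data has a vanishing third eigenvalue
  B <- matrix(rnorm(30), 15, 2)
  planar <- cbind(B, B[, 1] + 2 * B[, 2], 0.5 * B[, 1] - B[, 2])
  prp <- pca_project(planar)
  expect_lt(prp$eigenvalues[3] / prp$eigenvalues[1], 1e-12)
  # rotations preserve eigenvalues
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  prq <- pca_project(X %*% Q)
  expect_equal(prq$eigenvalues, pr$eigenvalues, tolerance = 1e-8)
  expect_error(pca_project(X[, 1:2]), "feature dimensions")
  expect_error(pca_project(X[1:3, ]), "4 samples")
})

test_that("extended neighbourhoods include distance ties beyond k", {
  # collinear points at distances 1 and 2 from the query
  f <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_equal(extended_knn(1, f, k = 1), 2L)
  expect_equal(sort(extended_knn(1, f, k = 2)), c(2L, 3L))
  # two points tied at the k-th distance are both included
  ft <- cbind(c(0, 1, -1, 5), c(0, 0, 0, 0))
  expect_equal(sort(extended_knn(1, ft, k = 1)), c(2L, 3L))
  expect_error(extended_knn(1, f, k = 3), "k must lie")
  expect_error(extended_knn(1, f, k = 0), "k must lie")
})

test_that("extended neighbourhoods match the counting oracle and are monotone", {
  set.seed(23)
  f <- matrix(sample(0:4, 60, TRUE), 30, 2) # integer grid forces many ties
  for (q in c(1, 7, 30)) {
    prev <- integer(0)
    for (k in 1:29) {
      tau <- sort(extended_knn(q, f, k))
      d <- sqrt(colSums((t(f) - f[q, ])^2)); d[q] <- Inf
      oracle <- sort(setdiff(which(vapply(seq_along(d), function(i)
        is.finite(d[i]) && sum(d < d[i]) < k, TRUE)), q))
      expect_identical(tau, oracle)
      expect_gte(length(tau), k)
      expect_true(all(prev %in% tau)) # monotone in k
      prev <- tau
    }
  }
})

test_that("neighbourhood votes break ties toward the lower class", {
  expect_equal(knn_classify(c("b", "b", "b"))$class, "b")
  expect_equal(knn_classify(c("a", "b", "b"))$class, "b")
  tie <- knn_classify(c("a", "a", "b", "b"))
  expect_equal(tie$class, "a")
  expect_true(tie$tie)
  expect_false(knn_classify(c("a", "b", "b"))$tie)
  expect_error(knn_classify(character(0)), "empty")
})

test_that("the accuracy curve matches the brute-force vote and its regimes", {
  set.seed(29)
  # two far-separated balanced clusters
  n2 <- 10
  f <- rbind(matrix(rnorm(n2 * 2, 0), n2, 2),
             matrix(rnorm(n2 * 2, 50), n2, 2))
  lab <- rep(c("alert", "drowsy"), each = n2)
  cv <- knn_sigma_curve(f, lab, grid_step = 10)
  # low k: perfect homogeneous concentration
  expect_equal(cv$accuracy_at_k[cv$k_percent_grid <= 40], rep(100, 4))
  # k = 100%: equals the exhaustive vote (balanced classes -> tie rule)
  full <- oracle_knn_accuracy(f, lab, k = 2 * n2 - 1)
  expect_equal(cv$accuracy_at_k[cv$k_percent_grid == 100], full)
  expect_equal(cv$summary_P, mean(cv$accuracy_at_k))
  # random instance agrees with the oracle at every grid point
  fr <- matrix(sample(0:3, 48, TRUE), 24, 2)
  lr <- sample(c("alert", "drowsy"), 24, TRUE)
  if (length(unique(lr)) == 2) {
    cr <- knn_sigma_curve(fr, lr, grid_step = 20)
    for (gi in seq_along(cr$k_percent_grid)) {
      k <- max(1, round(cr$k_percent_grid[gi] / 100 * 23))
      expect_equal(cr$accuracy_at_k[gi], oracle_knn_accuracy(fr, lr, k))
    }
  }
  expect_error(knn_sigma_curve(f, rep("alert", 2 * n2)), "both classes")
  expect_error(knn_sigma_curve(f[1:4, ], lab[1:4]), "n >= 10")
})

test_that("permuted labels give chance-level curves", {
  # Labels with a clear majority margin (24 vs 16): a label permutation
  # destroys the geometry-label link, so the curve must hover near the
  # majority rate (low k drifts toward the match probability p^2 + q^2,
  # high k toward the majority vote). Averaging permutations tightens the
  # Monte-Carlo band. Exactly balanced labels are avoided because the
  # leave-one-out vote then turns anti-predictive at k near n - 1 (the
  # query's own class is always one vote short).
  set.seed(37)
  f <- rbind(matrix(rnorm(20 * 4, 0), 20, 4),
             matrix(rnorm(20 * 4, 6), 20, 4))
  base <- rep(c("alert", "drowsy"), c(24, 16))
  majority <- 100 * 24 / 40
  curves <- sapply(1:3, function(i) {
    knn_sigma_curve(f, sample(base), grid_step = 10)$accuracy_at_k
  })
  avg <- rowMeans(curves)
  expect_true(all(abs(avg - majority) < 20))
  expect_lt(abs(mean(avg) - majority), 12)
})

test_that("the feature cloud plot draws every point in its class colour", {
  set.seed(41)
  X <- matrix(rnorm(60), 20, 3)
  pr <- pca_project(cbind(X, X[, 1]))
  lab <- rep(c("alert", "drowsy"), 10)
  path <- tempfile(fileext = ".png")
  res <- plot_feature_cloud(pr, lab, path = path)
  expect_true(file.exists(path) && file.size(path) > 0)
  unlink(path)
  pdf(NULL)
  res <- plot_feature_cloud(pr, lab)
  dev.off()
  expect_equal(nrow(res), 20)
  expect_equal(unname(res$col), ifelse(lab == "drowsy", "red", "blue"))
  # empty selection: no crash
  pr0 <- pr; pr0$projected <- pr$projected[0, , drop = FALSE]
  pdf(NULL)
  expect_no_error(plot_feature_cloud(pr0, character(0)))
  dev.off()
})
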