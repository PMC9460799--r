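# Feature-space diagnostics: penultimate-layer extraction, 3-component
# PCA visualization, and the KNN-Sigma curve — leave-one-out tie-aware
# k-nearest-neighbour accuracy traced over k as a percentage of sample
# size. Low-k accuracy reflects homogeneous within-class concentration;
# high-k accuracy reflects heterogeneous between-class separation.

#' Extract hidden-layer features for a batch of inputs
#'
#' One row per frame: the post-activation output of the 512-unit fully
#' connected layer (the 2-unit logit layer would make a 3-component PCA
#' degenerate, so the wide layer is used; `layer = "logits"` is available
#' for comparison).
#'
#' @param weights trained `cnn_weights`.
#' @param x `(H, W, 3, N)` inputs.
#' @param labels,subject_ids carried through into the result.
#' @param layer `"dense1"` (default) or `"logits"`.
#' @return a `feature_matrix` list: `features` (n x d), `labels`,
#'   `subject_ids`.
#' @export
extract_features <- function(weights, x, labels = NULL, subject_ids = NULL,
                             layer = c("dense1", "logits")) {
  layer <- match.arg(layer)
  pred <- cnn_predict(weights, x)
  f <- if (layer == "dense1") pred$features else pred$logits
  n <- nrow(f)
  structure(list(features = f,
                 labels = if (is.null(labels)) rep(NA, n) else labels,
                 subject_ids = if (is.null(subject_ids)) rep(NA_integer_, n)
                               else subject_ids),
            class = "feature_matrix")
}

#' Write / read a feature matrix as CSV (`subject_id,label,f0..f<d-1>`)
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_features_csv <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, label = fm$labels,
                   fm$features)
  names(df)[-(1:2)] <- paste0("f", seq_len(ncol(fm$features)) - 1L)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(features = as.matrix(df[, -(1:2), drop = FALSE]),
                 labels = df$label, subject_ids = df$subject_id),
            class = "feature_matrix")
}

#' Top-3 principal-component projection of a feature matrix
#'
#' Features are mean-centered, the covariance eigendecomposition is taken
#' (via [stats::prcomp()]), and the scores on the top three components
#' are returned with eigenvalues sorted in descending order.
#'
#' @param features n x d numeric matrix (or a `feature_matrix`), with
#'   `n >= 4` and `d >= 3`.
#' @param n_components number of components (default 3).
#' @return a `pca_projection` list: `components` (d x 3, orthonormal),
#'   `projected` (n x 3), `eigenvalues` (descending).
#' @export
pca_project <- function(features, n_components = 3L) {
  if (inherits(features, "feature_matrix")) features <- features$features
  features <- as.matrix(features)
  if (ncol(features) < n_components)
    stop("need at least ", n_components, " feature dimensions")
  if (nrow(features) < 4L) stop("need at least 4 samples")
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  structure(list(components = pc$rotation[, k, drop = FALSE],
                 projected = pc$x[, k, drop = FALSE],
                 eigenvalues = pc$sdev[k]^2),
            class = "pca_projection")
}

#' Extended k-nearest neighbourhood of one point
#'
#' All points (excluding the query itself — leave-one-out) whose
#' Euclidean distance to the query does not exceed the k-th-nearest
#' distance. Distance ties at the threshold are all included, so the
#' neighbourhood can hold more than `k` points.
#'
#' @param query index of the query point.
#' @param features n x d matrix.
#' @param k neighbourhood order, `1 <= k <= n - 1`.
#' @return integer vector of neighbour indices.
#' @export
extended_knn <- function(query, features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(query >= 1, query <= n)
  if (k < 1 || k > n - 1) stop("k must lie in [1, n - 1]")
  d <- sqrt(colSums((t(features) - features[query, ])^2))
  d[query] <- Inf
  eps <- sort(d)[k]
  setdiff(which(d <= eps), query)
}

#' Majority vote over a neighbourhood
#'
#' Ties are broken deterministically in favour of the lower class index;
#' the tie is flagged.
#'
#' @param neighbour_labels labels (factor or vector) of the neighbourhood.
#' @param class_levels ordered class levels (defines the tie-break order);
#'   defaults to the sorted unique labels.
#' @return list with `class` and `tie` (logical).
#' @export
knn_classify <- function(neighbour_labels, class_levels = NULL) {
  if (length(neighbour_labels) == 0L) stop("empty neighbourhood")
  if (is.null(class_levels))
    class_levels <- if (is.factor(neighbour_labels)) levels(neighbour_labels)
                    else sort(unique(as.character(neighbour_labels)))
  votes <- table(factor(as.character(neighbour_labels), levels = class_levels))
  top <- which(votes == max(votes))
  list(class = class_levels[top[1]], tie = length(top) > 1L)
}

#' KNN-Sigma curve: leave-one-out accuracy across k-percentages
#'
#' For each k-percentage on the grid, `k = max(1, round(pct/100 * (n-1)))`
#' and every point is classified by the tie-aware vote of its extended
#' k-neighbourhood. The curve's low-k end measures homogeneous
#' concentration, its high-k end heterogeneous separation; `summary_P`
#' is the mean accuracy over the grid.
#'
#' @param features n x d matrix or `feature_matrix` (`n >= 10`).
#' @param labels class labels (ignored when `features` carries them).
#' @param grid_step k-percentage step (default 1, grid 1..100).
#' @return a `knn_sigma_curve` list: `k_percent_grid`, `accuracy_at_k`
#'   (percent), `summary_P`, `n`, `tie_count`.
#' @export
knn_sigma_curve <- function(features, labels = NULL, grid_step = 1) {
  if (inherits(features, "feature_matrix")) {
    if (is.null(labels)) labels <- features$labels
    features <- features$features
  }
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n >= 10, length(labels) == n)
  labels <- as.character(labels)
  class_levels <- sort(unique(labels))
  if (length(class_levels) < 2L) stop("both classes must be present")
  grid <- seq(grid_step, 100, by = grid_step)
  # per-query distances via the same expression as extended_knn(), so
  # floating-point ties are judged identically on both routes
  tf <- t(features)
  D <- matrix(0, n, n)
  for (q in seq_len(n)) D[q, ] <- sqrt(colSums((tf - features[q, ])^2))
  diag(D) <- Inf
  # per query: neighbour distances sorted once, labels in that order
  ord <- apply(D, 1, order)          # n x n, column per query
  sorted_d <- apply(D, 1, sort)      # n x n, column per query
  correct <- matrix(FALSE, n, length(grid))
  tie_count <- 0L
  lab_idx <- match(labels, class_levels)
  for (q in seq_len(n)) {
    dq <- sorted_d[, q][seq_len(n - 1)]
    lq <- lab_idx[ord[, q][seq_len(n - 1)]]
    votes <- apply(outer(lq, seq_along(class_levels), "=="), 2, cumsum)
    for (gi in seq_along(grid)) {
      k <- max(1L, round(grid[gi] / 100 * (n - 1)))
      m <- findInterval(dq[k], dq) # last index with distance <= d_(k)
      v <- votes[m, ]
      top <- which(v == max(v))
      if (length(top) > 1L) tie_count <- tie_count + 1L
      correct[q, gi] <- class_levels[top[1]] == labels[q]
    }
  }
  acc <- 100 * colMeans(correct)
  structure(list(k_percent_grid = grid, accuracy_at_k = acc,
                 summary_P = mean(acc), n = n, tie_count = tie_count),
            class = "knn_sigma_curve")
}

#' Write a KNN-Sigma curve as CSV (`k_percent,accuracy`)
#' @param curve a `knn_sigma_curve`.
#' @param path CSV path.
#' @export
write_knn_sigma_csv <- function(curve, path) {
  write.csv(data.frame(k_percent = curve$k_percent_grid,
                       accuracy = curve$accuracy_at_k),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' 3-D scatter of projected features (drowsy red, alert blue)
#'
#' Orthographic 3-D projection drawn with base graphics; the drowsy class
#' is plotted in red, alert in blue, other labels in grey.
#'
#' @param projection a `pca_projection`.
#' @param labels per-point labels.
#' @param path optional PNG path.
#' @param theta,phi view angles (degrees).
#' @export
plot_feature_cloud <- function(projection, labels, path = NULL,
                               theta = 35, phi = 20) {
  stopifnot(inherits(projection, "pca_projection"))
  p <- projection$projected
  labels <- as.character(labels)
  cols <- ifelse(labels == "drowsy", "red",
                 ifelse(labels == "alert", "blue", "grey40"))
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  if (nrow(p) == 0L) {
    graphics::plot.new()
    graphics::title("feature cloud (empty)")
    return(invisible(NULL))
  }
  rng <- apply(p, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  u <- sweep(sweep(p, 2, rng[1, ]), 2, span, "/") # unit cube
  t <- theta * pi / 180; f <- phi * pi / 180
  x2 <- u[, 1] * cos(t) - u[, 2] * sin(t)
  y2 <- (u[, 1] * sin(t) + u[, 2] * cos(t)) * sin(f) + u[, 3] * cos(f)
  graphics::plot(x2, y2, col = cols, pch = 19, cex = 0.6,
                 xlab = "PC1-PC2 plane", ylab = "PC3 axis",
                 main = "feature cloud (red = drowsy, blue = alert)")
  invisible(data.frame(x = x2, y = y2, col = cols))
}
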