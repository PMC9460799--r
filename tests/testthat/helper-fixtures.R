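# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic dataset reused across module tests.
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_dataset(8, 4, effect_size = 3, seed = 42)
  }
  .fixture_env$small
}

# A reduced network (2 filters per conv, 4 hidden units) on a small input.
toy_model <- function(seed = 7L) {
  init_toy_weights(c(8L, 8L, 3L), filters1 = 2L, filters2 = 2L,
                   units = 4L, seed = seed)
}

random_image <- function(shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(shape)), shape)
}

# Independent tie-aware leave-one-out k-NN oracle: a point is a neighbour
# of the query iff strictly fewer than k points are strictly closer.
# Returns the predicted label for one query at one k.
oracle_knn_vote <- function(features, labels, query, k) {
  d <- sqrt(colSums((t(features) - features[query, ])^2))
  d[query] <- Inf
  members <- which(vapply(seq_along(d), function(i)
    is.finite(d[i]) && sum(d < d[i]) < k, TRUE))
  members <- setdiff(members, query)
  lv <- sort(unique(as.character(labels)))
  votes <- table(factor(as.character(labels[members]), levels = lv))
  lv[which.max(votes)] # which.max takes the first (lower) index on ties
}

# Oracle leave-one-out accuracy (percent) at a single k.
oracle_knn_accuracy <- function(features, labels, k) {
  n <- nrow(features)
  pred <- vapply(seq_len(n), function(q)
    oracle_knn_vote(features, labels, q, k), "")
  100 * mean(pred == as.character(labels))
}

# Mann-Whitney concordant-pair AUC oracle.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}
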