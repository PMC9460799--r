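# Weight containers and R-side forward machinery. The heavy batched
# training loop lives in src/cnn.cpp; everything here is either setup,
# a thin wrapper, or the per-image head used for attention gradients.

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dims)
}

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       mean = rep(0, channels), var = rep(1, channels))
}

#' Initialize network weights for a model specification
#'
#' Fan-based (Glorot) uniform initialization for convolution and dense
#' weights, zeros for biases, and identity batch-normalization parameters.
#' Deterministic under `seed`.
#'
#' @param spec a `cnn_spec` from [build_model()].
#' @param seed integer seed.
#' @return a `cnn_weights` list (one entry per parameterized layer) with
#'   the input shape attached as an attribute.
#' @export
init_cnn_weights <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  flat <- spec$flatten_size
  w <- list(
    bn0 = bn_init(3L),
    conv1 = list(W = glorot_uniform(5 * 5 * 3, 5 * 5 * 32, c(5, 5, 3, 32)),
                 b = numeric(32)),
    bn1 = bn_init(32L),
    conv2 = list(W = glorot_uniform(3 * 3 * 32, 3 * 3 * 64, c(3, 3, 32, 64)),
                 b = numeric(64)),
    bn2 = bn_init(64L),
    dense1 = list(W = glorot_uniform(flat, 512, c(flat, 512)), b = numeric(512)),
    bn3 = bn_init(512L),
    dense2 = list(W = glorot_uniform(512, 2, c(512, 2)), b = numeric(2))
  )
  attr(w, "input_shape") <- spec$input_shape
  class(w) <- "cnn_weights"
  w
}

#' Build a reduced ("toy") weight set with custom layer widths
#'
#' Same layer sequence as the full network but with configurable filter
#' and unit counts; the engine reads all sizes from the weight arrays.
#' Used for cheap gradient checking and unit tests.
#'
#' @param input_shape `(rows, cols, 3)`.
#' @param filters1,filters2 convolution channel counts.
#' @param units hidden dense width.
#' @param seed integer seed.
#' @export
init_toy_weights <- function(input_shape, filters1 = 2L, filters2 = 2L,
                             units = 8L, seed = 1L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, input_shape[3] == 3L)
  set.seed(seed)
  flat <- (input_shape[1] %/% 4L) * (input_shape[2] %/% 4L) * filters2
  w <- list(
    bn0 = bn_init(3L),
    conv1 = list(W = glorot_uniform(5 * 5 * 3, 5 * 5 * filters1,
                                    c(5, 5, 3, filters1)),
                 b = numeric(filters1)),
    bn1 = bn_init(filters1),
    conv2 = list(W = glorot_uniform(3 * 3 * filters1, 3 * 3 * filters2,
                                    c(3, 3, filters1, filters2)),
                 b = numeric(filters2)),
    bn2 = bn_init(filters2),
    dense1 = list(W = glorot_uniform(flat, units, c(flat, units)),
                  b = numeric(units)),
    bn3 = bn_init(units),
    dense2 = list(W = glorot_uniform(units, 2, c(units, 2)), b = numeric(2))
  )
  attr(w, "input_shape") <- input_shape
  class(w) <- "cnn_weights"
  w
}

as_image_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a (H, W, 3) image or (H, W, 3, N) batch")
  x
}

#' Run the network in inference mode
#'
#' @param weights a `cnn_weights` list.
#' @param x a `(H, W, 3)` image or `(H, W, 3, N)` batch, values in `[0, 1]`.
#' @param return_A also return the last convolution's linear output
#'   (the feature maps Grad-CAM attributes over).
#' @param batch_size internal batch size.
#' @return list with `probs`, `logits`, `features` (hidden dense layer,
#'   post-activation) and optionally `A`.
#' @export
cnn_predict <- function(weights, x, return_A = FALSE, batch_size = 64L) {
  x <- as_image_batch(x)
  cpp_cnn_predict(weights, x, batch_size = batch_size, return_A = return_A)
}

bn_infer_r <- function(x, p, eps = 1e-3) {
  batch_norm(x, p$gamma, p$beta, eps = eps, training = FALSE,
             running_mean = p$mean, running_var = p$var)
}

bn_infer_arr <- function(a, p, eps = 1e-3) {
  d <- dim(a)
  m <- matrix(a, prod(d[1:2]), d[3])
  array(bn_infer_r(m, p, eps), d)
}

#' Reference forward pass composed from the layer primitives
#'
#' A pure-R inference-mode forward pass built from [conv2d()],
#' [leaky_relu()], [batch_norm()], [maxpool2()] and [softmax()]. It is the
#' cross-check route for the compiled engine and the forward map used by
#' finite-difference tests; the compiled path in [cnn_predict()] is the
#' production route.
#'
#' @param weights a `cnn_weights` list.
#' @param img single `(H, W, 3)` image.
#' @return list with `probs`, `logits`, `features`, `A` (last-conv linear
#'   output) and the intermediates needed to differentiate the head.
#' @export
cnn_forward_reference <- function(weights, img) {
  stopifnot(length(dim(img)) == 3L)
  x <- bn_infer_arr(img, weights$bn0)
  x <- conv2d(x, weights$conv1$W, weights$conv1$b)
  x <- array(leaky_relu(x), dim(x))
  x <- bn_infer_arr(x, weights$bn1)
  x <- maxpool2(x)
  A <- conv2d(x, weights$conv2$W, weights$conv2$b)
  head_forward(weights, A, detail = TRUE)
}

#' Network head: from the last-conv feature maps to the logits
#'
#' Forward map from the last convolution's linear output `A` through
#' LeakyReLU, batch normalization (inference statistics), max pooling,
#' the hidden dense layer and the output layer. Kept in R so attention
#' gradients can be computed analytically and finite-difference checked
#' against the very same map.
#'
#' @param weights a `cnn_weights` list.
#' @param A `(i, j, k)` last-conv linear output for one input.
#' @param detail also return probabilities, features and the
#'   intermediates needed to differentiate the head.
#' @return the logit vector, or a detailed list with `detail = TRUE`.
#' @export
head_forward <- function(weights, A, detail = FALSE) {
  dA <- dim(A)
  a2 <- array(leaky_relu(A), dA)
  b2 <- bn_infer_arr(a2, weights$bn2)
  pooled <- maxpool2(b2, return_index = TRUE)
  flat <- as.numeric(pooled$output)
  z1 <- as.numeric(flat %*% weights$dense1$W) + weights$dense1$b
  f1 <- leaky_relu(z1)
  h <- as.numeric(bn_infer_r(matrix(f1, 1), weights$bn3))
  logits <- as.numeric(h %*% weights$dense2$W) + weights$dense2$b
  if (!detail) return(logits)
  list(probs = softmax(logits), logits = logits, features = f1, A = A,
       pool_index = pooled$index, z1 = z1, pooled_dim = dim(pooled$output))
}

# Analytic gradient of a class score with respect to A. `use_softmax`
# switches the attributed score from the pre-softmax logit (standard
# Grad-CAM practice) to the softmax probability.
head_gradient <- function(weights, A, class_index, use_softmax = FALSE) {
  fw <- head_forward(weights, A, detail = TRUE)
  K <- length(fw$logits)
  if (class_index < 1L || class_index > K)
    stop("class index out of range")
  dlogits <- numeric(K)
  if (use_softmax) {
    p <- fw$probs
    dlogits <- -p[class_index] * p
    dlogits[class_index] <- dlogits[class_index] + p[class_index]
  } else {
    dlogits[class_index] <- 1
  }
  eps <- 1e-3
  dh <- as.numeric(weights$dense2$W %*% dlogits)
  df1 <- dh * weights$bn3$gamma / sqrt(weights$bn3$var + eps)
  dz1 <- df1 * ifelse(fw$z1 >= 0, 1, 0.3)
  dflat <- as.numeric(weights$dense1$W %*% dz1)
  # un-flatten and route back through the pooling argmax
  dpool <- array(dflat, fw$pooled_dim)
  dA <- array(0, dim(A))
  d <- dim(A)
  for (ch in seq_len(d[3])) {
    sl <- matrix(0, d[1], d[2])
    sl[as.vector(fw$pool_index[, , ch])] <- as.vector(dpool[, , ch])
    dA[, , ch] <- sl
  }
  scale2 <- weights$bn2$gamma / sqrt(weights$bn2$var + eps)
  dA <- sweep(dA, 3, scale2, "*")
  dA * ifelse(A >= 0, 1, 0.3)
}
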