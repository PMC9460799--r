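#' Zero-padding width for a "same" convolution
#'
#' Stride-1 convolution with padding `(k - 1) / 2` on every edge preserves
#' the spatial size of its input. Only odd kernels are supported, which is
#' all this architecture uses (5x5 and 3x3).
#'
#' @param kernel_size odd integer kernel width.
#' @return integer padding width.
#' @examples
#' same_padding(5) # 2
#' same_padding(3) # 1
#' @export
same_padding <- function(kernel_size) {
  stopifnot(is.numeric(kernel_size), length(kernel_size) == 1L,
            kernel_size >= 1, kernel_size == as.integer(kernel_size))
  if (kernel_size %% 2 == 0)
    stop("even kernel sizes are not supported by same padding")
  as.integer((kernel_size - 1) / 2)
}

#' Leaky rectified linear unit
#'
#' `x` for non-negative inputs, `alpha * x` otherwise. The network uses
#' `alpha = 0.3` throughout.
#'
#' @param x numeric vector/array.
#' @param alpha slope below zero.
#' @export
leaky_relu <- function(x, alpha = 0.3) {
  ifelse(x >= 0, x, alpha * x)
}

#' Overflow-safe softmax
#'
#' Exponentials are taken after subtracting the row maximum, so arbitrarily
#' large logits are handled without overflow; outputs are positive and each
#' row sums to one.
#'
#' @param x numeric vector, or matrix with one sample per row.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(is.finite(x)))
    e <- exp(x - apply(x, 1, max))
    e / rowSums(e)
  } else {
    stopifnot(all(is.finite(x)))
    e <- exp(x - max(x))
    e / sum(e)
  }
}

#' Stride-1 same-padded 2-D convolution (cross-correlation)
#'
#' Deep-learning convention: the kernel is not flipped. Output spatial size
#' equals input spatial size; the operation is linear in the input.
#'
#' @param input `(rows, cols, c_in)` array.
#' @param kernels `(k, k, c_in, c_out)` array.
#' @param bias length-`c_out` vector (default zeros).
#' @return `(rows, cols, c_out)` array.
#' @export
conv2d <- function(input, kernels, bias = NULL) {
  stopifnot(length(dim(input)) == 3L, length(dim(kernels)) == 4L)
  if (dim(kernels)[3] != dim(input)[3])
    stop("kernel input channels do not match the image channels")
  if (is.null(bias)) bias <- numeric(dim(kernels)[4])
  cpp_conv2d(input, kernels, as.numeric(bias))
}

#' Batch normalization over the sample dimension
#'
#' In training mode, each channel (column) is standardized with the batch
#' mean and biased batch variance, then rescaled by the trainable `gamma`
#' and `beta`; in inference mode the supplied running statistics are used.
#' `eps` is added to the variance so constant channels normalize to `beta`
#' rather than dividing by zero.
#'
#' @param x matrix, samples in rows and channels in columns.
#' @param gamma,beta per-channel scale and shift.
#' @param eps variance floor.
#' @param training use batch statistics (`TRUE`) or running ones.
#' @param running_mean,running_var running statistics (inference mode).
#' @return matrix of the same shape as `x`.
#' @export
batch_norm <- function(x, gamma = NULL, beta = NULL, eps = 1e-3,
                       training = TRUE, running_mean = NULL,
                       running_var = NULL) {
  x <- as.matrix(x)
  nc <- ncol(x)
  if (is.null(gamma)) gamma <- rep(1, nc)
  if (is.null(beta)) beta <- rep(0, nc)
  stopifnot(length(gamma) == nc, length(beta) == nc)
  if (training) {
    if (nrow(x) < 2L) stop("training-mode batch normalization needs a batch of at least 2")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2) # biased variance
  } else {
    if (is.null(running_mean) || is.null(running_var))
      stop("inference-mode batch normalization needs running statistics")
    mu <- running_mean
    v <- running_var
  }
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

LAYER_SEQUENCE <- function(input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  h2 <- h %/% 2L; w2 <- w %/% 2L
  h4 <- h2 %/% 2L; w4 <- w2 %/% 2L
  flat <- h4 * w4 * 64L
  list(
    list(name = "bn_input", kind = "bn", channels = 3L,
         out_shape = c(h, w, 3L)),
    list(name = "conv1", kind = "conv", kernel = c(5L, 5L), channels = 32L,
         activation = "leaky_relu", stride = 1L, out_shape = c(h, w, 32L)),
    list(name = "bn1", kind = "bn", channels = 32L, out_shape = c(h, w, 32L)),
    list(name = "pool1", kind = "maxpool", pool = c(2L, 2L), stride = 2L,
         out_shape = c(h2, w2, 32L)),
    list(name = "conv2", kind = "conv", kernel = c(3L, 3L), channels = 64L,
         activation = "leaky_relu", stride = 1L, out_shape = c(h2, w2, 64L)),
    list(name = "bn2", kind = "bn", channels = 64L, out_shape = c(h2, w2, 64L)),
    list(name = "pool2", kind = "maxpool", pool = c(2L, 2L), stride = 2L,
         out_shape = c(h4, w4, 64L)),
    list(name = "flatten", kind = "flatten", out_shape = flat),
    list(name = "dense1", kind = "dense", units = 512L,
         activation = "leaky_relu", out_shape = 512L),
    list(name = "bn3", kind = "bn", channels = 512L, out_shape = 512L),
    list(name = "dense2", kind = "softmax_dense", units = 2L,
         activation = "softmax", out_shape = 2L)
  )
}

#' Build the drowsiness-network specification for a given input shape
#'
#' The layer sequence is fixed — input batch normalization, a 32-kernel
#' 5x5 convolution, a 64-kernel 3x3 convolution (both same-padded, stride
#' 1, LeakyReLU, each followed by batch normalization and 2x2 max
#' pooling), a 512-unit fully connected layer with batch normalization,
#' and a 2-unit softmax head. Only the input shape varies between the
#' face (28x28), eye (32x64), fusion (32x96) and gender-signal (37x64)
#' variants.
#'
#' @param input_shape integer `(rows, cols, 3)`.
#' @return a `cnn_spec` object: layer list plus derived sizes.
#' @export
build_model <- function(input_shape) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || input_shape[3] != 3L)
    stop("input_shape must be (rows, cols, 3)")
  if (any(input_shape[1:2] < 4L))
    stop("input rows and cols must be at least 4 to survive two poolings")
  layers <- LAYER_SEQUENCE(input_shape)
  flat <- layers[[8]]$out_shape
  structure(list(input_shape = input_shape, layers = layers,
                 flatten_size = flat),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> input (%s), flatten %d\n",
              paste(x$input_shape, collapse = ", "), x$flatten_size))
  pc <- count_parameters(x)
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %-10s %-14s params %s\n", l$name, l$kind,
                format(pc$per_layer[[l$name]], big.mark = ",")))
  }
  cat(sprintf("  trainable %s | non-trainable %s | total %s\n",
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ","),
              format(pc$total, big.mark = ",")))
  invisible(x)
}

#' Exact per-layer parameter accounting
#'
#' Convolutions contribute `k*k*c_in*c_out + c_out`, dense layers
#' `n_in*n_out + n_out`, and each batch-normalization channel contributes
#' four parameters — trainable scale and shift plus non-trainable running
#' mean and variance. Pooling and flatten layers are parameter-free.
#'
#' @param spec a `cnn_spec` from [build_model()].
#' @return a `parameter_count` object with `per_layer`, `trainable`,
#'   `non_trainable` and `total` fields.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  per_layer <- integer(0)
  trainable <- 0; non_trainable <- 0
  c_in <- spec$input_shape[3]
  flat <- spec$flatten_size
  prev_units <- NULL
  for (l in spec$layers) {
    n <- switch(l$kind,
      bn = 4L * l$channels,
      conv = {
        k <- l$kernel[1]
        n <- k * k * c_in * l$channels + l$channels
        c_in <- l$channels
        n
      },
      maxpool = 0L,
      flatten = { prev_units <- flat; 0L },
      dense = ,
      softmax_dense = {
        n <- prev_units * l$units + l$units
        prev_units <- l$units
        n
      })
    if (l$kind == "bn") {
      trainable <- trainable + 2L * l$channels
      non_trainable <- non_trainable + 2L * l$channels
    } else {
      trainable <- trainable + n
    }
    per_layer[[l$name]] <- as.integer(n)
  }
  structure(list(per_layer = per_layer,
                 trainable = as.integer(trainable),
                 non_trainable = as.integer(non_trainable),
                 total = as.integer(trainable + non_trainable)),
            class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  df <- data.frame(layer = names(x$per_layer),
                   parameters = format(unname(x$per_layer), big.mark = ","))
  print(df, row.names = FALSE)
  cat(sprintf("Trainable:     %s\n", format(x$trainable, big.mark = ",")))
  cat(sprintf("Non-trainable: %s\n", format(x$non_trainable, big.mark = ",")))
  cat(sprintf("Total:         %s\n", format(x$total, big.mark = ",")))
  invisible(x)
}
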