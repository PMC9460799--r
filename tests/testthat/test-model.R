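# Layer primitives and the exact parameter accounting.

test_that("same padding preserves spatial size and rejects even kernels", {
  expect_identical(same_padding(5), 2L)
  expect_identical(same_padding(3), 1L)
  expect_identical(same_padding(1), 0L)
  expect_error(same_padding(4), "even")
  # size preservation through an actual convolution
  img <- random_image(c(9, 11, 2), seed = 1)
  K <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  expect_identical(dim(conv2d(img, K)), c(9L, 11L, 3L))
})

test_that("leaky ReLU has slope 0.3 below zero", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-10), -3)
  expect_equal(leaky_relu(0), 0)
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x), ifelse(x < 0, 0.3 * x, x))
})

test_that("softmax is normalized, symmetric and shift-invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  a <- c(0.3, -1.2); shift <- 57
  expect_equal(softmax(a + shift), softmax(a))
  x <- c(1, 2, 3)
  expect_equal(softmax(x), exp(x) / sum(exp(x)))
  # overflow safety and exact normalization on random logits
  set.seed(3)
  for (i in 1:20) {
    z <- rnorm(4, sd = 200)
    s <- softmax(z)
    expect_true(all(s > 0))
    expect_lt(abs(sum(s) - 1), 1e-12)
  }
})

test_that("conv2d matches the brute-force sliding double sum", {
  set.seed(11)
  img <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  K <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  b <- rnorm(2)
  out <- conv2d(img, K, b)
  p <- 2L
  brute <- array(0, c(8, 8, 2))
  for (co in 1:2) for (m in 1:8) for (n in 1:8) {
    s <- b[co]
    for (j in 1:5) for (k in 1:5) for (ci in 1:3) {
      mm <- m + j - 1 - p; nn <- n + k - 1 - p
      if (mm >= 1 && mm <= 8 && nn >= 1 && nn <= 8)
        s <- s + img[mm, nn, ci] * K[j, k, ci, co]
    }
    brute[m, n, co] <- s
  }
  expect_lt(max(abs(out - brute)), 1e-10)
})

test_that("conv2d identity kernel and constant-sum cases", {
  img <- random_image(c(6, 6, 1), seed = 2)
  K <- array(0, c(3, 3, 1, 1)); K[2, 2, 1, 1] <- 1
  expect_equal(conv2d(img, K), img, tolerance = 1e-12)
  const <- array(2.5, c(6, 6, 1))
  ones <- array(1, c(3, 3, 1, 1))
  out <- conv2d(const, ones)
  expect_equal(out[3, 3, 1], 9 * 2.5) # interior pixel
  # channel mismatch rejected
  expect_error(conv2d(random_image(c(4, 4, 2)), ones), "channels")
})

test_that("batch normalization standardizes in training mode", {
  set.seed(5)
  x <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  y <- batch_norm(x, eps = 1e-8)
  expect_lt(max(abs(colMeans(y))), 1e-10)
  expect_equal(unname(apply(y, 2, function(v) mean((v - mean(v))^2))),
               rep(1, 4), tolerance = 1e-4)
  # constant channel -> beta everywhere (eps prevents division by zero)
  xc <- cbind(rep(4, 10), rnorm(10))
  yc <- batch_norm(xc, gamma = c(2, 2), beta = c(0.7, 0))
  expect_equal(yc[, 1], rep(0.7, 10), tolerance = 1e-8)
  expect_error(batch_norm(matrix(1, 1, 2)), "batch")
  expect_error(batch_norm(x, training = FALSE), "running")
})

test_that("build_model derives the flatten size from two pool halvings", {
  expect_equal(build_model(c(28, 28, 3))$flatten_size, 3136)
  expect_equal(build_model(c(32, 64, 3))$flatten_size, 8192)
  expect_equal(build_model(c(32, 96, 3))$flatten_size, 12288)
  expect_equal(build_model(c(37, 64, 3))$flatten_size, 9 * 16 * 64)
  expect_error(build_model(c(3, 28, 3)), "at least 4")
  expect_error(build_model(c(28, 28, 1)), "rows, cols, 3")
  spec <- build_model(c(28, 28, 3))
  expect_length(spec$layers, 11)
})

test_that("parameter accounting matches the published per-layer counts", {
  pc <- count_parameters(build_model(c(28, 28, 3)))
  expect_equal(pc$per_layer[["bn_input"]], 12L)
  expect_equal(pc$per_layer[["conv1"]], 2432L)
  expect_equal(pc$per_layer[["bn1"]], 128L)
  expect_equal(pc$per_layer[["pool1"]], 0L)
  expect_equal(pc$per_layer[["conv2"]], 18496L)
  expect_equal(pc$per_layer[["bn2"]], 256L)
  expect_equal(pc$per_layer[["dense1"]], 1606144L)
  expect_equal(pc$per_layer[["bn3"]], 2048L)
  expect_equal(pc$per_layer[["dense2"]], 1026L)
  expect_equal(pc$trainable, 1629320L)
  expect_equal(pc$total, pc$trainable + pc$non_trainable)
})

test_that("analytic counts equal enumeration of the concrete weight arrays", {
  for (shape in list(c(28L, 28L, 3L), c(32L, 64L, 3L), c(32L, 96L, 3L),
                     c(16L, 16L, 3L))) {
    spec <- build_model(shape)
    w <- init_cnn_weights(spec, seed = 1)
    trainable <- 0; non_trainable <- 0
    for (nm in names(w)) {
      l <- w[[nm]]
      if (grepl("^bn", nm)) {
        trainable <- trainable + length(l$gamma) + length(l$beta)
        non_trainable <- non_trainable + length(l$mean) + length(l$var)
      } else {
        trainable <- trainable + length(l$W) + length(l$b)
      }
    }
    pc <- count_parameters(spec)
    expect_equal(pc$trainable, trainable)
    expect_equal(pc$non_trainable, non_trainable)
    expect_equal(sum(pc$per_layer), pc$total)
  }
})

test_that("compiled inference agrees with the primitive-composed forward pass", {
  spec <- build_model(c(16, 16, 3))
  w <- init_cnn_weights(spec, seed = 2)
  set.seed(9)
  for (i in 1:3) {
    x <- random_image(c(16, 16, 3))
    a <- cnn_predict(w, x)
    b <- cnn_forward_reference(w, x)
    expect_lt(max(abs(a$probs - b$probs)), 1e-10)
    expect_lt(max(abs(a$logits - b$logits)), 1e-10)
    expect_lt(max(abs(a$features - b$features)), 1e-10)
  }
  # last-conv feature maps agree too
  x <- random_image(c(16, 16, 3))
  a <- cnn_predict(w, x, return_A = TRUE)
  b <- cnn_forward_reference(w, x)
  expect_lt(max(abs(a$A[, , , 1] - b$A)), 1e-10)
})
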