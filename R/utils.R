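#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' (generator, fold splitting, weight initialization, training) draws its
#' own sub-seed with a distinct stream tag so that stages can be re-run in
#' isolation without perturbing one another.
#'
#' @param seed master seed (integer).
#' @param stream small non-negative integer tag for the consuming stage.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; multiplier from MINSTD
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + 1 + as.numeric(stream) * 104729) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Bilinear resize of a 2-D or 3-D image array
#'
#' Uses the corner-aligned convention: output corner pixels reproduce input
#' corner pixels exactly, and a source grid of size one along an axis yields
#' a constant output along that axis.
#'
#' @param img numeric matrix or `(rows, cols, channels)` array.
#' @param out_rows,out_cols output size.
#' @return resized array of the same rank as the input.
#' @export
resize_bilinear <- function(img, out_rows, out_cols) {
  stopifnot(is.numeric(img), out_rows >= 1, out_cols >= 1)
  d <- dim(img)
  if (is.null(d) || length(d) < 2L) stop("img must be a matrix or 3-D array")
  was_matrix <- length(d) == 2L
  if (was_matrix) dim(img) <- c(d, 1L)
  d <- dim(img)
  if (d[1] == out_rows && d[2] == out_cols) {
    out <- img
  } else {
    src_r <- if (out_rows == 1L || d[1] == 1L) rep(0, out_rows) else
      (seq_len(out_rows) - 1) * (d[1] - 1) / (out_rows - 1)
    src_c <- if (out_cols == 1L || d[2] == 1L) rep(0, out_cols) else
      (seq_len(out_cols) - 1) * (d[2] - 1) / (out_cols - 1)
    r0 <- pmin(floor(src_r), d[1] - 1); r1 <- pmin(r0 + 1, d[1] - 1)
    c0 <- pmin(floor(src_c), d[2] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
    fr <- src_r - r0; fc <- src_c - c0
    out <- array(0, c(out_rows, out_cols, d[3]))
    wr0 <- 1 - fr; wc0 <- 1 - fc
    for (ch in seq_len(d[3])) {
      sl <- img[, , ch, drop = FALSE]
      dim(sl) <- d[1:2]
      # four-corner blend, vectorized over the output grid
      A <- sl[r0 + 1, c0 + 1, drop = FALSE]
      B <- sl[r0 + 1, c1 + 1, drop = FALSE]
      C <- sl[r1 + 1, c0 + 1, drop = FALSE]
      D <- sl[r1 + 1, c1 + 1, drop = FALSE]
      Wc0 <- matrix(wc0, out_rows, out_cols, byrow = TRUE)
      Wc1 <- matrix(fc, out_rows, out_cols, byrow = TRUE)
      Wr0 <- matrix(wr0, out_rows, out_cols)
      Wr1 <- matrix(fr, out_rows, out_cols)
      out[, , ch] <- Wr0 * (A * Wc0 + B * Wc1) + Wr1 * (C * Wc0 + D * Wc1)
    }
  }
  if (was_matrix) out[, , 1, drop = TRUE] else out
}

#' 2x2 max pooling with stride 2 (reference implementation)
#'
#' Trailing odd rows or columns are dropped, matching the network engine.
#'
#' @param x `(rows, cols, channels)` array or matrix.
#' @param return_index also return the linear (row, col) source index of
#'   each pooled maximum, needed for gradient routing.
#' @return pooled array; with `return_index = TRUE`, a list with `output`
#'   and `index` (same shape as `output`, linear index into each channel).
#' @export
maxpool2 <- function(x, return_index = FALSE) {
  d <- dim(x)
  was_matrix <- length(d) == 2L
  if (was_matrix) { dim(x) <- c(d, 1L); d <- dim(x) }
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  stopifnot(H2 >= 1, W2 >= 1)
  out <- array(0, c(H2, W2, d[3]))
  idx <- array(0L, c(H2, W2, d[3]))
  rs <- 2L * seq_len(H2) - 1L; cs <- 2L * seq_len(W2) - 1L
  for (ch in seq_len(d[3])) {
    sl <- x[, , ch]
    cand <- list(sl[rs, cs, drop = FALSE], sl[rs + 1L, cs, drop = FALSE],
                 sl[rs, cs + 1L, drop = FALSE], sl[rs + 1L, cs + 1L, drop = FALSE])
    off_r <- c(0L, 1L, 0L, 1L); off_c <- c(0L, 0L, 1L, 1L)
    best <- cand[[1]]; which_best <- array(1L, dim(best))
    for (t in 2:4) {
      gt <- cand[[t]] > best
      best[gt] <- cand[[t]][gt]
      which_best[gt] <- t
    }
    out[, , ch] <- best
    src_r <- matrix(rs, H2, W2) + matrix(off_r[which_best], H2, W2)
    src_c <- matrix(cs, H2, W2, byrow = TRUE) + matrix(off_c[which_best], H2, W2)
    idx[, , ch] <- src_r + (src_c - 1L) * d[1]
  }
  if (was_matrix) {
    out <- out[, , 1, drop = TRUE]
    idx <- idx[, , 1, drop = TRUE]
  }
  if (return_index) list(output = out, index = idx) else out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write an image array to PNG
#'
#' @param img `(rows, cols, 3)` array, either integer intensities in
#'   `[0, 255]` or reals in `[0, 1]`.
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  if (max(img) > 1) img <- img / 255
  png::writePNG(clamp(img, 0, 1), target = path)
  invisible(path)
}

#' Read a PNG image as an intensity array
#'
#' @param path PNG file.
#' @return `(rows, cols, 3)` numeric array with values in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}
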