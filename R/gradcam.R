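# Gradient-weighted class activation mapping. The class score (the
# pre-softmax logit by default) is differentiated with respect to the
# last convolution's feature maps A; each channel's gradient is averaged
# over space into a weight alpha_k, and the heatmap is the pixelwise
# ReLU of the alpha-weighted channel sum, up-sampled to the input size.

#' Channel weights from class-score gradients
#'
#' Each channel's weight is the spatial mean of the gradient of the class
#' score with respect to that channel of the last-conv feature maps.
#'
#' @param gradient `(i, j, k)` array of score gradients.
#' @param A optional matching feature-map array (shape check only).
#' @return length-`k` numeric vector.
#' @export
alpha_weights <- function(gradient, A = NULL) {
  stopifnot(length(dim(gradient)) == 3L)
  if (!is.null(A) && !identical(dim(A), dim(gradient)))
    stop("gradient grid must be shaped like the feature maps")
  apply(gradient, 3, mean)
}

#' Raw attention map from feature maps and channel weights
#'
#' Pixelwise ReLU of the weighted channel sum, so the map is everywhere
#' non-negative and positively homogeneous in the feature maps.
#'
#' @param A `(i, j, k)` feature-map array.
#' @param alpha length-`k` channel weights.
#' @return `(i, j)` non-negative matrix.
#' @export
gradcam_map <- function(A, alpha) {
  d <- dim(A)
  stopifnot(length(d) == 3L)
  if (length(alpha) != d[3])
    stop("alpha length must equal the channel count")
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + alpha[k] * A[, , k]
  pmax(m, 0)
}

#' Exact gradients of a class score w.r.t. the last-conv feature maps
#'
#' Runs the network head analytically (inference-mode batch statistics)
#' and backpropagates the class score — the pre-softmax logit by default,
#' or the softmax probability with `use_softmax = TRUE` — down to the
#' last convolution's linear output.
#'
#' @param weights trained `cnn_weights`.
#' @param img single `(H, W, 3)` input, values in `[0, 1]`.
#' @param class_index 1-based class (1 = alert, 2 = drowsy).
#' @param use_softmax attribute the softmax probability instead of the
#'   logit.
#' @return list with `A` (feature maps) and `gradient` (same shape).
#' @export
class_gradients <- function(weights, img, class_index,
                            use_softmax = FALSE) {
  fw <- cnn_forward_reference(weights, img)
  list(A = fw$A,
       gradient = head_gradient(weights, fw$A, class_index,
                                use_softmax = use_softmax))
}

#' Grad-CAM heatmap for one input image
#'
#' @param weights trained `cnn_weights`.
#' @param img single `(H, W, 3)` input in `[0, 1]`.
#' @param class_index 1-based class; `NULL` uses the predicted class.
#' @param use_softmax see [class_gradients()].
#' @return a `gradcam_heatmap` list: `raw_map` (last-conv resolution),
#'   `upsampled_map` (input resolution, bilinear), `class_index`,
#'   `probs`.
#' @export
gradcam <- function(weights, img, class_index = NULL, use_softmax = FALSE) {
  fw <- cnn_forward_reference(weights, img)
  if (is.null(class_index)) class_index <- which.max(fw$probs)
  grad <- head_gradient(weights, fw$A, class_index, use_softmax = use_softmax)
  alpha <- alpha_weights(grad)
  raw <- gradcam_map(fw$A, alpha)
  up <- resize_bilinear(raw, dim(img)[1], dim(img)[2])
  structure(list(raw_map = raw, upsampled_map = pmax(up, 0),
                 class_index = class_index, probs = fw$probs),
            class = "gradcam_heatmap")
}

#' Render a heatmap over its input image
#'
#' Min-max normalizes the up-sampled map to `[0, 1]` (an all-zero map
#' stays flat), colours it with a blue-to-red map (low to high
#' attention), and alpha-blends it onto the input.
#'
#' @param heatmap a `gradcam_heatmap` (or a non-negative matrix, which is
#'   up-sampled to the image size first).
#' @param img the `(H, W, 3)` input image in `[0, 1]`.
#' @param alpha blend weight of the heatmap.
#' @param path optional PNG output path.
#' @return `(H, W, 3)` overlay array in `[0, 1]` (invisibly if written).
#' @export
upsample_overlay <- function(heatmap, img, alpha = 0.5, path = NULL) {
  m <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$upsampled_map
       else resize_bilinear(heatmap, dim(img)[1], dim(img)[2])
  stopifnot(all(m >= 0))
  rng <- range(m)
  norm <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(m), ncol(m))
  # blue (low) -> red (high)
  col <- array(0, c(dim(norm), 3))
  col[, , 1] <- norm
  col[, , 2] <- 0.2 * (1 - abs(2 * norm - 1))
  col[, , 3] <- 1 - norm
  out <- clamp((1 - alpha) * img + alpha * col, 0, 1)
  if (!is.null(path)) {
    write_image_png(out, path)
    return(invisible(out))
  }
  out
}

#' Share of heatmap mass falling inside a region mask
#'
#' The chance baseline is the mask's area fraction: attention is
#' concentrated on the region when `mask_fraction` exceeds
#' `mask_area_fraction`. A heatmap with zero total mass yields fraction 0
#' with `degenerate = TRUE`.
#'
#' @param heatmap a `gradcam_heatmap` or non-negative matrix matching the
#'   mask shape.
#' @param mask logical matrix.
#' @return an `attention_score` list: `mask_fraction`,
#'   `mask_area_fraction`, `degenerate`.
#' @export
attention_fraction <- function(heatmap, mask) {
  m <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$upsampled_map
       else heatmap
  if (!identical(dim(m), dim(mask)))
    stop("mask must match the heatmap shape")
  total <- sum(m)
  frac <- if (total <= 0) 0 else sum(m[mask]) / total
  structure(list(mask_fraction = frac,
                 mask_area_fraction = mean(mask),
                 degenerate = total <= 0),
            class = "attention_score")
}
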