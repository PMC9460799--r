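# Construction of the three network input variants from a raw frame plus
# eye landmarks: face thumbnail (28x28), stacked eye pair (32x64), and
# their horizontal fusion (32x96), plus the gender-signal variant that
# appends a constant strip below the eye pair. Coordinates are 0-based
# with half-open [start, end) boxes in (row, col) order throughout.

#' Eye bounding box from landmark extrema
#'
#' The box spans the landmark minima/maxima per axis (half-open), expanded
#' by `margin` times the box extent on each side, and clipped to the image
#' when `image_size` is given. `margin = 0` reproduces the raw extrema box.
#'
#' @param points matrix of `(row, col)` landmark coordinates (0-based),
#'   at least two distinct points.
#' @param margin non-negative expansion fraction per axis.
#' @param image_size optional `(rows, cols)` for clipping.
#' @return a `bounding_box` list with `row_start`, `row_end`, `col_start`,
#'   `col_end` (0-based, half-open).
#' @export
eye_box_from_landmarks <- function(points, margin = 0, image_size = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, margin >= 0)
  if (nrow(points) < 2L || nrow(unique(points)) < 2L)
    stop("need at least two distinct landmark points to form a box")
  rmin <- min(points[, 1]); rmax <- max(points[, 1])
  cmin <- min(points[, 2]); cmax <- max(points[, 2])
  if (rmin == rmax && cmin == cmax) stop("degenerate landmark box")
  rext <- rmax + 1 - rmin; cext <- cmax + 1 - cmin
  rs <- floor(rmin - margin * rext); re <- ceiling(rmax + 1 + margin * rext)
  cs <- floor(cmin - margin * cext); ce <- ceiling(cmax + 1 + margin * cext)
  if (!is.null(image_size)) {
    rs <- max(rs, 0); cs <- max(cs, 0)
    re <- min(re, image_size[1]); ce <- min(ce, image_size[2])
  }
  structure(list(row_start = as.integer(rs), row_end = as.integer(re),
                 col_start = as.integer(cs), col_end = as.integer(ce)),
            class = "bounding_box")
}

#' Crop a box out of an image and resize it bilinearly
#'
#' @param image `(rows, cols, channels)` array or matrix.
#' @param box a `bounding_box` (0-based, half-open), fully inside the image.
#' @param out_size `(rows, cols)` of the output.
#' @return resized block with the same channel count.
#' @export
crop_resize <- function(image, box, out_size) {
  stopifnot(inherits(box, "bounding_box"))
  d <- dim(image)
  if (box$row_start >= box$row_end || box$col_start >= box$col_end)
    stop("empty bounding box")
  if (box$row_start < 0 || box$col_start < 0 ||
      box$row_end > d[1] || box$col_end > d[2])
    stop("bounding box extends outside the image")
  rows <- (box$row_start + 1L):box$row_end
  cols <- (box$col_start + 1L):box$col_end
  block <- if (length(d) == 3L) image[rows, cols, , drop = FALSE]
           else image[rows, cols, drop = FALSE]
  resize_bilinear(block, out_size[1], out_size[2])
}

#' Stack two resized eye blocks into one 32x64 eye-pair image
#'
#' Rows 0-15 hold the left eye, rows 16-31 the right eye (a recorded
#' convention; the composite is lossless either way).
#'
#' @param left,right `16x64x3` blocks.
#' @return `32x64x3` array.
#' @export
stack_eyes <- function(left, right) {
  if (!identical(dim(left), c(16L, 64L, 3L)) ||
      !identical(dim(right), c(16L, 64L, 3L)))
    stop("eye blocks must be 16x64x3")
  out <- array(0, c(32L, 64L, 3L))
  out[1:16, , ] <- left
  out[17:32, , ] <- right
  out
}

#' Split an eye-pair image back into its two eye blocks
#' @param eyes `32x64x3` eye-pair image.
#' @return list with `left` and `right` `16x64x3` blocks.
#' @export
split_eyes <- function(eyes) {
  if (!identical(dim(eyes), c(32L, 64L, 3L))) stop("eye pair must be 32x64x3")
  list(left = eyes[1:16, , , drop = FALSE],
       right = eyes[17:32, , , drop = FALSE])
}

#' Fuse a 32x32 face thumbnail with a 32x64 eye pair
#'
#' Horizontal concatenation — face in columns 0-31, eyes in columns 32-95 —
#' yielding the 32x96 fusion input.
#'
#' @param face32 `32x32x3` face block.
#' @param eyes `32x64x3` eye-pair image.
#' @return `32x96x3` fusion image.
#' @export
build_fusion <- function(face32, eyes) {
  if (!identical(dim(face32), c(32L, 32L, 3L)))
    stop("face block must be 32x32x3")
  if (!identical(dim(eyes), c(32L, 64L, 3L)))
    stop("eye pair must be 32x64x3")
  out <- array(0, c(32L, 96L, 3L))
  out[, 1:32, ] <- face32
  out[, 33:96, ] <- eyes
  out
}

#' Extract the face / eye blocks of a fusion image
#' @param fusion `32x96x3` fusion image.
#' @return list with `face` (`32x32x3`) and `eyes` (`32x64x3`).
#' @export
split_fusion <- function(fusion) {
  if (!identical(dim(fusion), c(32L, 96L, 3L))) stop("fusion image must be 32x96x3")
  list(face = fusion[, 1:32, , drop = FALSE],
       eyes = fusion[, 33:96, , drop = FALSE])
}

#' Append a constant gender-signal strip below an eye-pair image
#'
#' A 5-row strip spanning the full 64-pixel width, value 0 for male and
#' 255 for female (scaled to the input's intensity range), giving a
#' `37x64x3` input.
#'
#' @param eyes `32x64x3` eye-pair image.
#' @param gender `"male"` or `"female"`.
#' @return `37x64x3` array.
#' @export
build_gender_signal <- function(eyes, gender) {
  if (!identical(dim(eyes), c(32L, 64L, 3L))) stop("eye pair must be 32x64x3")
  gender <- match.arg(gender, c("male", "female"))
  hi <- if (max(eyes) <= 1) 1 else 255
  out <- array(0, c(37L, 64L, 3L))
  out[1:32, , ] <- eyes
  out[33:37, , ] <- if (gender == "male") 0 else hi
  out
}

#' Remove the gender-signal strip
#' @param img `37x64x3` gender-signal image.
#' @return the `32x64x3` eye-pair image.
#' @export
strip_gender_signal <- function(img) {
  if (!identical(dim(img), c(37L, 64L, 3L))) stop("expected a 37x64x3 image")
  img[1:32, , , drop = FALSE]
}

#' Read a landmark CSV (`eye,point_index,row,col`) into a landmark set
#' @param path CSV file.
#' @return list with `left` and `right` point matrices.
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("eye", "point_index", "row", "col") %in% names(df)))
  out <- lapply(split(df, df$eye), function(d)
    as.matrix(d[order(d$point_index), c("row", "col")]))
  if (!all(c("left", "right") %in% names(out)))
    stop("landmark CSV must contain both 'left' and 'right' eyes")
  out[c("left", "right")]
}

# Map a binary mask through crop+resize; bilinear then 0.5 threshold.
transform_mask <- function(mask, box, out_size) {
  m <- crop_resize(matrix(as.numeric(mask), nrow(mask)), box, out_size)
  m >= 0.5
}

#' Build a network input (and matched region masks) from one frame
#'
#' Runs the full preprocessing of a raw frame: eye boxes from the
#' landmark extrema (expanded by `margin`), per-eye crops resized to
#' 16x64 and stacked, face resized to 28x28 (face input) or 32x32
#' (fusion), and optional gender strip. Pixel intensities are rescaled
#' to `[0, 1]` for the network; the input-side batch normalization makes
#' the result insensitive to this affine choice. The frame's sclera and
#' eye-region masks are carried through the same geometry so attention
#' scores can be computed in input coordinates.
#'
#' @param frame a `synthetic_frame` (or a list with the same fields).
#' @param input_type `"face"`, `"eye"`, `"fusion"` or `"eye+gender"`.
#' @param margin landmark-box expansion fraction.
#' @return list with `x` (the input array, values in `[0, 1]`), `masks`
#'   (list of logical `sclera` and `eye` masks in input coordinates),
#'   `label`, `gender`, `subject_id`.
#' @export
preprocess_frame <- function(frame, input_type = c("eye", "face", "fusion",
                                                   "eye+gender"),
                             margin = 0.3) {
  input_type <- match.arg(input_type)
  img <- frame$image / 255
  d <- dim(img)
  full_box <- structure(list(row_start = 0L, row_end = d[1],
                             col_start = 0L, col_end = d[2]),
                        class = "bounding_box")

  make_eyes <- function() {
    blocks <- list(); smasks <- list(); emasks <- list()
    for (side in c("left", "right")) {
      pts <- frame$landmarks[[side]] - 1 # 1-based raster coords -> 0-based
      box <- eye_box_from_landmarks(pts, margin = margin, image_size = d[1:2])
      blocks[[side]] <- crop_resize(img, box, c(16L, 64L))
      smasks[[side]] <- transform_mask(frame$sclera_masks[[side]], box, c(16L, 64L))
      emasks[[side]] <- transform_mask(frame$eye_masks[[side]], box, c(16L, 64L))
    }
    list(x = stack_eyes(blocks$left, blocks$right),
         sclera = rbind(smasks$left, smasks$right),
         eye = rbind(emasks$left, emasks$right))
  }

  out <- switch(input_type,
    face = {
      x <- crop_resize(img, full_box, c(28L, 28L))
      list(x = x,
           masks = list(
             sclera = transform_mask(frame$sclera_mask, full_box, c(28L, 28L)),
             eye = transform_mask(frame$eye_region_mask, full_box, c(28L, 28L))))
    },
    eye = {
      e <- make_eyes()
      list(x = e$x, masks = list(sclera = e$sclera, eye = e$eye))
    },
    fusion = {
      e <- make_eyes()
      face32 <- crop_resize(img, full_box, c(32L, 32L))
      scl <- cbind(matrix(FALSE, 32L, 32L), e$sclera)
      eye <- cbind(transform_mask(frame$eye_region_mask, full_box, c(32L, 32L)),
                   e$eye)
      list(x = build_fusion(face32, e$x), masks = list(sclera = scl, eye = eye))
    },
    `eye+gender` = {
      e <- make_eyes()
      x <- build_gender_signal(e$x, frame$gender)
      pad <- matrix(FALSE, 5L, 64L)
      list(x = x, masks = list(sclera = rbind(e$sclera, pad),
                               eye = rbind(e$eye, pad)))
    })
  out$label <- frame$label
  out$gender <- frame$gender
  out$subject_id <- frame$subject_id
  out
}

#' Input shape of each network input variant
#' @param input_type one of `"face"`, `"eye"`, `"fusion"`, `"eye+gender"`.
#' @return integer `(rows, cols, 3)`.
#' @export
input_shape_for <- function(input_type = c("eye", "face", "fusion",
                                           "eye+gender")) {
  input_type <- match.arg(input_type)
  switch(input_type,
         face = c(28L, 28L, 3L),
         eye = c(32L, 64L, 3L),
         fusion = c(32L, 96L, 3L),
         `eye+gender` = c(37L, 64L, 3L))
}

#' Assemble frames into a `(H, W, 3, N)` training array
#'
#' @param frames list of `synthetic_frame` objects.
#' @param input_type input variant, see [preprocess_frame()].
#' @param margin landmark-box expansion fraction.
#' @return list with `x` (input array), `labels` (factor alert/drowsy),
#'   `genders`, `subject_ids`, and `masks` (per-frame mask lists).
#' @export
prepare_inputs <- function(frames, input_type = "eye", margin = 0.3) {
  pp <- lapply(frames, preprocess_frame, input_type = input_type,
               margin = margin)
  shp <- dim(pp[[1]]$x)
  x <- array(0, c(shp, length(pp)))
  for (i in seq_along(pp)) x[, , , i] <- pp[[i]]$x
  list(x = x,
       labels = factor(vapply(pp, `[[`, "", "label"),
                       levels = c("alert", "drowsy")),
       genders = factor(vapply(pp, `[[`, "", "gender"),
                        levels = c("male", "female")),
       subject_ids = vapply(pp, `[[`, 0L, "subject_id"),
       masks = lapply(pp, `[[`, "masks"))
}
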