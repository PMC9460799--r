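# Parametric schematic face generator. Every downstream stage of the
# package is exercised on these images: the drowsiness signal lives only
# in the eye region (sclera red excess and eyelid aperture), while an
# optional gender-correlated hair band gives the face context an identity
# cue that is independent of drowsiness by construction. The rendering is
# deliberately schematic, not photorealistic: the point is that the
# generating parameters and region masks are known exactly.

# Population parameters of the two classes. Class means differ by
# `effect_size` within-class standard deviations on both cues.
SYN_REDNESS_ALERT <- 0.10
SYN_REDNESS_SD <- 0.05
SYN_APERTURE_ALERT <- 0.80
SYN_APERTURE_SD <- 0.05
SYN_SCLERA_BASE <- 0.50      # green/blue level of the sclera; red = base + redness
SYN_FRAME_REDNESS_SD <- 0.02 # frame-to-frame jitter around the subject mean
SYN_FRAME_APERTURE_SD <- 0.03

#' Draw a synthetic subject profile
#'
#' Assigns class and gender (unless forced) and draws the subject-level
#' sclera-redness and eyelid-aperture means from the class populations:
#' drowsy subjects have higher redness and smaller aperture, with class
#' means separated by `effect_size` within-class standard deviations.
#' With `effect_size = 0` the two classes are identical in expectation.
#'
#' @param subject_id integer identifier.
#' @param class_balance probability of the drowsy class in `(0, 1)`.
#' @param effect_size class separation in within-class SD units (>= 0).
#' @param seed integer seed; the same `(subject_id, seed)` always yields
#'   the same profile.
#' @param noise_sd per-pixel rendering noise SD on the `[0, 1]` intensity
#'   scale; must be positive.
#' @param drowsy_class optionally force `"alert"` or `"drowsy"`.
#' @param gender optionally force `"male"` or `"female"`.
#' @return a `subject_profile` list.
#' @export
generate_subject <- function(subject_id, class_balance = 0.5, effect_size = 3,
                             seed = 1L, noise_sd = 0.02, drowsy_class = NULL,
                             gender = NULL) {
  stopifnot(effect_size >= 0, class_balance > 0, class_balance < 1)
  if (noise_sd <= 0)
    stop("noise_sd must be positive")
  set.seed(derive_seed(seed, stream = 100L + as.integer(subject_id)))
  if (is.null(drowsy_class))
    drowsy_class <- if (runif(1) < class_balance) "drowsy" else "alert"
  drowsy_class <- match.arg(drowsy_class, c("alert", "drowsy"))
  if (is.null(gender)) gender <- if (runif(1) < 0.5) "male" else "female"
  gender <- match.arg(gender, c("male", "female"))
  drowsy <- drowsy_class == "drowsy"
  redness <- rnorm(1, SYN_REDNESS_ALERT + drowsy * effect_size * SYN_REDNESS_SD,
                   SYN_REDNESS_SD)
  aperture <- rnorm(1, SYN_APERTURE_ALERT - drowsy * effect_size * SYN_APERTURE_SD,
                    SYN_APERTURE_SD)
  structure(list(
    subject_id = as.integer(subject_id),
    gender = gender,
    drowsy_class = drowsy_class,
    sclera_redness_mean = clamp(redness, 0, 1 - SYN_SCLERA_BASE),
    eyelid_aperture_mean = clamp(aperture, 0, 1),
    face_tone = runif(1, 0.40, 0.75),
    hair_jitter = runif(1, -0.05, 0.05),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "subject_profile")
}

ellipse_mask <- function(rows, cols, center, semi) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

# Six landmarks per eye, taken from the rasterized full-eye ellipse so the
# landmark extrema box always contains the eye-region mask.
eye_landmarks <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  rmin <- min(w[, 1]); rmax <- max(w[, 1])
  cmin <- min(w[, 2]); cmax <- max(w[, 2])
  rbind(
    c(rmin, round(mean(w[w[, 1] == rmin, 2]))),   # top lid point
    c(rmax, round(mean(w[w[, 1] == rmax, 2]))),   # bottom lid point
    c(round(mean(w[w[, 2] == cmin, 1])), cmin),   # inner/outer corner
    c(round(mean(w[w[, 2] == cmax, 1])), cmax),
    c(rmin + (rmax - rmin) %/% 4, cmin + (cmax - cmin) %/% 4),
    c(rmin + (rmax - rmin) %/% 4, cmax - (cmax - cmin) %/% 4)
  )
}

#' Render one synthetic frame for a subject
#'
#' Draws a schematic face — skin ellipse at the subject's tone, a hair
#' band whose darkness encodes gender when the gender confound is on, a
#' mouth — and two eyes. Each eye is a sclera ellipse tinted red by the
#' subject's redness, a dark iris disc, and an upper eyelid occluding
#' `1 - aperture` of the eye. Per-frame jitter moves the eye centers and
#' perturbs redness/aperture slightly; i.i.d. Gaussian pixel noise is
#' added before quantization to 8-bit intensities. Deterministic in
#' `(profile, frame_index)`.
#'
#' @param profile a `subject_profile`.
#' @param frame_index non-negative frame number.
#' @param image_size `(rows, cols)`, each at least 64.
#' @param gender_confound render the gender-dependent hair band; when
#'   `FALSE` the hair band is the same mid-grey for everyone, so no class
#'   or gender signal exists outside the eye regions.
#' @return a `synthetic_frame` list: `image` (integer `(rows, cols, 3)`
#'   in 0..255), `landmarks` (left/right point matrices), `sclera_mask`,
#'   `eye_region_mask`, per-eye masks, `label`, `gender`, `subject_id`.
#' @export
render_frame <- function(profile, frame_index, image_size = c(128L, 128L),
                         gender_confound = TRUE) {
  stopifnot(inherits(profile, "subject_profile"))
  if (frame_index < 0) stop("frame_index must be non-negative")
  image_size <- as.integer(image_size)
  if (any(image_size < 64L)) stop("image_size must be at least (64, 64)")
  H <- image_size[1]; W <- image_size[2]
  set.seed(derive_seed(profile$seed,
                       stream = 1000L + profile$subject_id * 211L +
                         as.integer(frame_index)))

  redness <- clamp(profile$sclera_redness_mean + rnorm(1, 0, SYN_FRAME_REDNESS_SD),
                   0, 1 - SYN_SCLERA_BASE)
  aperture <- if (profile$eyelid_aperture_mean == 0) 0 else # fully closed stays closed
    clamp(profile$eyelid_aperture_mean + rnorm(1, 0, SYN_FRAME_APERTURE_SD), 0, 1)
  jit <- round(rnorm(2, 0, 1.2)) # shared eye-row / per-frame column jitter

  img <- array(0.12, c(H, W, 3)) # dark background
  face <- ellipse_mask(H, W, c(0.54 * H, 0.50 * W), c(0.40 * H, 0.32 * W))
  for (ch in 1:3) { sl <- img[, , ch]; sl[face] <- profile$face_tone; img[, , ch] <- sl }

  hair_level <- if (gender_confound) {
    (if (profile$gender == "male") 0.15 else 0.75) + profile$hair_jitter
  } else 0.45
  # full-width band so the identity cue is prominent in the face context
  hair_rows <- max(1L, round(0.10 * H)):round(0.24 * H)
  hair <- matrix(FALSE, H, W); hair[hair_rows, ] <- TRUE
  for (ch in 1:3) { sl <- img[, , ch]; sl[hair] <- hair_level; img[, , ch] <- sl }

  mouth <- ellipse_mask(H, W, c(0.76 * H, 0.50 * W), c(0.02 * H, 0.10 * W))
  for (ch in 1:3) { sl <- img[, , ch]; sl[mouth] <- 0.25; img[, , ch] <- sl }

  eye_centers <- list(
    left  = c(0.44 * H + jit[1], 0.34 * W + jit[2]),
    right = c(0.44 * H + jit[1], 0.66 * W + jit[2])
  )
  semi <- c(0.055 * H, 0.085 * W)
  iris_r <- 0.030 * min(H, W)

  eye_masks <- list(); sclera_masks <- list(); landmarks <- list()
  for (side in c("left", "right")) {
    ctr <- eye_centers[[side]]
    eye <- ellipse_mask(H, W, ctr, semi)
    # eyelid: the top (1 - aperture) fraction of the eye stays skin-coloured
    lid_cut <- (ctr[1] - semi[1]) + (1 - aperture) * 2 * semi[1]
    rgrid <- matrix(seq_len(H), H, W)
    visible <- eye & (rgrid >= lid_cut)
    iris <- ellipse_mask(H, W, ctr, c(iris_r, iris_r)) & visible
    sclera <- visible & !iris
    for (ch in 1:3) {
      sl <- img[, , ch]
      base <- if (ch == 1) SYN_SCLERA_BASE + redness else SYN_SCLERA_BASE
      sl[sclera] <- base
      sl[iris] <- 0.08
      img[, , ch] <- sl
    }
    eye_masks[[side]] <- eye
    sclera_masks[[side]] <- sclera
    landmarks[[side]] <- eye_landmarks(eye)
  }

  img <- img + array(rnorm(H * W * 3, 0, profile$noise_sd), c(H, W, 3))
  img <- array(as.integer(round(clamp(img, 0, 1) * 255)), c(H, W, 3))

  structure(list(
    image = img,
    landmarks = landmarks[c("left", "right")],
    sclera_mask = sclera_masks$left | sclera_masks$right,
    eye_region_mask = eye_masks$left | eye_masks$right,
    eye_masks = eye_masks,
    sclera_masks = sclera_masks,
    label = profile$drowsy_class,
    gender = profile$gender,
    subject_id = profile$subject_id,
    frame_index = as.integer(frame_index)
  ), class = "synthetic_frame")
}

#' Generate a full synthetic dataset
#'
#' Draws `n_subjects` profiles with a fixed class split (the drowsy count
#' is `round(n_subjects * class_balance)`, so subject-level proportions
#' match `class_balance` to within `1/n_subjects`) and renders
#' `frames_per_subject` frames each. Genders are balanced within each
#' class. Optionally writes PNG frames and a `manifest.csv` with header
#' `subject_id,path,label,gender`.
#'
#' @param n_subjects at least 4 (so subject-level splitting is possible).
#' @param frames_per_subject frames rendered per subject.
#' @param class_balance drowsy fraction.
#' @param effect_size class separation (SD units).
#' @param seed master seed.
#' @param image_size frame size, at least `(64, 64)`.
#' @param gender_confound see [render_frame()].
#' @param noise_sd rendering noise SD.
#' @param dir if non-`NULL`, write PNGs and the manifest there.
#' @return list with `frames` (list of `synthetic_frame`), `manifest`
#'   (data.frame), and `profiles`.
#' @export
generate_dataset <- function(n_subjects, frames_per_subject,
                             class_balance = 0.5, effect_size = 3,
                             seed = 1L, image_size = c(128L, 128L),
                             gender_confound = TRUE, noise_sd = 0.02,
                             dir = NULL) {
  stopifnot(n_subjects >= 4, frames_per_subject >= 1)
  n_drowsy <- round(n_subjects * class_balance)
  set.seed(derive_seed(seed, stream = 7L))
  classes <- sample(rep(c("drowsy", "alert"),
                        c(n_drowsy, n_subjects - n_drowsy)))
  genders <- character(n_subjects)
  for (cl in c("alert", "drowsy")) {
    ids <- which(classes == cl)
    ng <- length(ids)
    genders[ids] <- sample(rep(c("male", "female"), length.out = ng))
  }
  profiles <- lapply(seq_len(n_subjects), function(i)
    generate_subject(i, class_balance, effect_size, seed = seed,
                     noise_sd = noise_sd, drowsy_class = classes[i],
                     gender = genders[i]))
  frames <- list(); rows <- list()
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("output directory is not writable: ", dir)
  }
  idx <- 1L
  for (p in profiles) {
    for (f in seq_len(frames_per_subject) - 1L) {
      fr <- render_frame(p, f, image_size, gender_confound)
      path <- sprintf("s%03d_f%03d.png", p$subject_id, f)
      if (!is.null(dir)) write_image_png(fr$image, file.path(dir, path))
      frames[[idx]] <- fr
      rows[[idx]] <- data.frame(subject_id = p$subject_id, path = path,
                                label = p$drowsy_class, gender = p$gender,
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  list(frames = frames, manifest = manifest, profiles = profiles)
}
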