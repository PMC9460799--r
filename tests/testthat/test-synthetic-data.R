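# The parametric generator: determinism, class-signal calibration, mask
# and landmark geometry, and confound structure.

test_that("profiles are deterministic and respect the zero-effect case", {
  p1 <- generate_subject(3, seed = 10)
  p2 <- generate_subject(3, seed = 10)
  expect_identical(p1, p2)
  p3 <- generate_subject(4, seed = 10)
  expect_false(identical(p1$sclera_redness_mean, p3$sclera_redness_mean))
  expect_error(generate_subject(1, noise_sd = 0), "noise_sd")
  # zero effect: class means coincide in expectation
  reds <- vapply(1:120, function(i)
    generate_subject(i, effect_size = 0, seed = 5,
                     drowsy_class = if (i %% 2) "alert" else "drowsy"
                     )$sclera_redness_mean, 0)
  cls <- rep(c("alert", "drowsy"), 60)
  smd <- abs(mean(reds[cls == "drowsy"]) - mean(reds[cls == "alert"])) /
    sd(reds)
  expect_lt(smd, 0.5)
})

test_that("class separation matches the requested effect size", {
  reds <- vapply(1:200, function(i)
    generate_subject(i, effect_size = 3, seed = 8,
                     drowsy_class = if (i <= 100) "alert" else "drowsy"
                     )$sclera_redness_mean, 0)
  aps <- vapply(1:200, function(i)
    generate_subject(i, effect_size = 3, seed = 8,
                     drowsy_class = if (i <= 100) "alert" else "drowsy"
                     )$eyelid_aperture_mean, 0)
  cls <- rep(c("alert", "drowsy"), each = 100)
  pooled <- function(x) sqrt(mean(tapply(x, cls, function(v)
    mean((v - mean(v))^2))))
  smd_red <- (mean(reds[cls == "drowsy"]) - mean(reds[cls == "alert"])) /
    pooled(reds)
  smd_ap <- (mean(aps[cls == "alert"]) - mean(aps[cls == "drowsy"])) /
    pooled(aps)
  expect_gt(smd_red, 2.5); expect_lt(smd_red, 3.5)
  expect_gt(smd_ap, 2.5); expect_lt(smd_ap, 3.5)
  # direction invariant: drowsy redder, less open
  expect_gt(min(reds[cls == "drowsy"]) + 0.2, min(reds[cls == "alert"]))
})

test_that("rendering is deterministic per (profile, frame) and frames differ", {
  p <- generate_subject(1, seed = 3)
  f1 <- render_frame(p, 2)
  f2 <- render_frame(p, 2)
  expect_identical(f1$image, f2$image)
  f3 <- render_frame(p, 3)
  expect_false(identical(f1$image, f3$image))
  expect_error(render_frame(p, -1), "non-negative")
  expect_error(render_frame(p, 0, image_size = c(32, 32)), "64")
})

test_that("degenerate aperture and redness render as specified", {
  p <- generate_subject(1, seed = 3)
  p$eyelid_aperture_mean <- 0
  f <- render_frame(p, 0)
  expect_equal(sum(f$sclera_mask), 0) # eye fully closed
  p2 <- generate_subject(2, seed = 3)
  p2$sclera_redness_mean <- 0
  f2 <- render_frame(p2, 0)
  rg <- f2$image[, , 1][f2$sclera_mask] - f2$image[, , 2][f2$sclera_mask]
  expect_lt(abs(mean(rg)), 0.05 * 255)
})

test_that("sclera red excess reproduces the redness parameter on pixels", {
  # many frames so the per-frame jitter averages out
  p <- generate_subject(1, seed = 6)
  p$sclera_redness_mean <- 0.3
  p$eyelid_aperture_mean <- 0.85
  diffs <- vapply(0:19, function(i) {
    f <- render_frame(p, i)
    mean(f$image[, , 1][f$sclera_mask] - f$image[, , 2][f$sclera_mask])
  }, 0)
  expect_equal(mean(diffs), 0.3 * 255, tolerance = 0.05 * 255 / (0.3 * 255))
})

test_that("masks and landmarks satisfy the geometric invariants", {
  ds <- small_dataset()
  for (f in ds$frames[seq(1, length(ds$frames), by = 5)]) {
    expect_true(all(f$sclera_mask[!f$eye_region_mask] == FALSE)) # subset
    d <- dim(f$image)
    for (side in c("left", "right")) {
      lm <- f$landmarks[[side]]
      em <- f$eye_masks[[side]]
      w <- which(em, arr.ind = TRUE)
      # landmarks inside the eye-region bounding box
      expect_true(all(lm[, 1] >= min(w[, 1]) & lm[, 1] <= max(w[, 1])))
      expect_true(all(lm[, 2] >= min(w[, 2]) & lm[, 2] <= max(w[, 2])))
      # landmark extrema box contains the mask's bounding box
      box <- eye_box_from_landmarks(lm - 1, margin = 0)
      expect_lte(box$row_start, min(w[, 1]) - 1)
      expect_gte(box$row_end, max(w[, 1]))
      expect_lte(box$col_start, min(w[, 2]) - 1)
      expect_gte(box$col_end, max(w[, 2]))
    }
  }
})

test_that("dataset generation counts, proportions and manifest determinism", {
  ds <- generate_dataset(8, 10, seed = 1)
  expect_equal(nrow(ds$manifest), 80)
  expect_setequal(names(ds$manifest), c("subject_id", "path", "label", "gender"))
  ds60 <- generate_dataset(60, 1, class_balance = 0.5, seed = 2)
  expect_equal(sum(ds60$manifest$label == "drowsy"), 30)
  # byte-identical manifest under the same seed
  d1 <- file.path(tempdir(), "synds1"); d2 <- file.path(tempdir(), "synds2")
  generate_dataset(4, 2, seed = 9, dir = d1)
  generate_dataset(4, 2, seed = 9, dir = d2)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  expect_true(file.exists(file.path(d1, "s001_f000.png")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("class signal stays in the eye region; gender only in the face", {
  ds_off <- generate_dataset(16, 2, seed = 21, gender_confound = FALSE)
  ds_on <- generate_dataset(16, 2, seed = 21, gender_confound = TRUE)
  region_mean <- function(f, region) {
    m <- if (region == "face") !f$eye_region_mask else f$eye_region_mask
    mean(f$image[, , 1][m])
  }
  summarize <- function(ds, region, by) {
    v <- vapply(ds$frames, region_mean, 0, region = region)
    g <- vapply(ds$frames, `[[`, "", by)
    tapply(v, g, mean)
  }
  # confound off: face region carries neither class nor gender signal
  fc <- summarize(ds_off, "face", "label")
  fg <- summarize(ds_off, "face", "gender")
  expect_lt(abs(diff(fc)), 6)
  expect_lt(abs(diff(fg)), 6)
  # eye region carries the class signal either way
  ec <- summarize(ds_on, "eye", "label")
  expect_gt(abs(diff(ec)), 4)
  # confound on: face region separates gender but still not class
  fg_on <- summarize(ds_on, "face", "gender")
  fc_on <- summarize(ds_on, "face", "label")
  expect_gt(abs(diff(fg_on)), 15)
  expect_lt(abs(diff(fc_on)), 6)
})
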