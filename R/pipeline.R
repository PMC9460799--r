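# End-to-end orchestration: simulate -> preprocess -> split -> train ->
# evaluate -> explain -> analyze, with one master seed driving every
# stage and a machine-readable summary. The companion command-line
# wrapper at inst/scripts/drowsecam exposes each stage as a subcommand.

#' Assemble a full run configuration
#'
#' All sub-seeds are derived from the master seed, so one integer pins
#' the whole run.
#'
#' @param input_type network input variant.
#' @param n_subjects,frames_per_subject synthetic dataset size.
#' @param class_balance,effect_size,noise_sd,image_size,gender_confound
#'   generator parameters, see [generate_dataset()].
#' @param target `"drowsiness"` (default) or `"gender"` — which label the
#'   classifier is trained on.
#' @param n_iterations number of 70/30 train/test resamples.
#' @param max_steps,batch_size,initial_lr,decay_steps,decay_rate training
#'   parameters (see [train_config()]; `NULL` decay keeps the per-input
#'   default).
#' @param n_gradcam number of test frames to render attention overlays
#'   for.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(input_type = "eye", n_subjects = 12L,
                       frames_per_subject = 6L, class_balance = 0.5,
                       effect_size = 3, noise_sd = 0.02,
                       image_size = c(128L, 128L), gender_confound = TRUE,
                       target = c("drowsiness", "gender"),
                       n_iterations = 4L, max_steps = 10000L,
                       batch_size = 32L, initial_lr = 0.01,
                       decay_steps = 1000L, decay_rate = NULL,
                       n_gradcam = 4L, seed = 1L) {
  target <- match.arg(target)
  cfg <- list(input_type = match.arg(input_type,
                                     c("eye", "face", "fusion", "eye+gender")),
              n_subjects = as.integer(n_subjects),
              frames_per_subject = as.integer(frames_per_subject),
              class_balance = class_balance, effect_size = effect_size,
              noise_sd = noise_sd, image_size = as.integer(image_size),
              gender_confound = isTRUE(gender_confound), target = target,
              n_iterations = as.integer(n_iterations),
              max_steps = as.integer(max_steps),
              batch_size = as.integer(batch_size),
              initial_lr = initial_lr, decay_steps = as.integer(decay_steps),
              decay_rate = decay_rate, n_gradcam = as.integer(n_gradcam),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
}

#' Parameter-count report for an input variant
#'
#' Builds the model specification for the requested input and prints the
#' exact per-layer and total parameter counts.
#'
#' @param input_type network input variant.
#' @param quiet suppress printing.
#' @return the `parameter_count`, invisibly.
#' @export
report_params <- function(input_type = c("eye", "face", "fusion",
                                         "eye+gender"),
                          quiet = FALSE) {
  input_type <- match.arg(input_type)
  shape <- input_shape_for(input_type)
  pc <- count_parameters(build_model(shape))
  if (!quiet) {
    cat(sprintf("Input: %s (%s)\n", input_type,
                paste(shape, collapse = ", ")))
    print(pc)
  }
  invisible(pc)
}

#' Run the full pipeline into an output directory
#'
#' Stages: synthetic dataset (+ manifest), preprocessing to the chosen
#' input variant, four stratified subject-level splits, per-iteration
#' training and evaluation, Grad-CAM overlays for a sample of the first
#' iteration's test frames, feature extraction with PCA plot, the
#' KNN-Sigma curve, and a summary JSON. Deterministic: the same config
#' produces byte-identical summaries.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if missing).
#' @param dry_run validate the configuration and print the stage plan
#'   without computing.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(cfg, out_dir, dry_run = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- c("simulate", "preprocess", "split", "train/eval", "gradcam",
              "features", "knn-sigma", "summary")
  if (dry_run) {
    cat("run plan:", paste(stages, collapse = " -> "), "\n")
    cat(sprintf("  %s input, %d subjects x %d frames, %d iterations, %d steps\n",
                cfg$input_type, cfg$n_subjects, cfg$frames_per_subject,
                cfg$n_iterations, cfg$max_steps))
    return(invisible(NULL))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_run_config(cfg, file.path(out_dir, "config.json"))
  stage <- "simulate"
  result <- tryCatch({
    ds <- generate_dataset(cfg$n_subjects, cfg$frames_per_subject,
                           class_balance = cfg$class_balance,
                           effect_size = cfg$effect_size,
                           seed = derive_seed(cfg$seed, 1L),
                           image_size = cfg$image_size,
                           gender_confound = cfg$gender_confound,
                           noise_sd = cfg$noise_sd)
    write.csv(ds$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE, quote = FALSE)

    stage <- "preprocess"
    prep <- prepare_inputs(ds$frames, cfg$input_type)
    y <- if (cfg$target == "gender") prep$genders else prep$labels
    manifest <- ds$manifest
    if (cfg$target == "gender") manifest$label <- manifest$gender

    stage <- "split"
    folds <- make_folds(manifest, seed = derive_seed(cfg$seed, 2L),
                        n_iterations = cfg$n_iterations)

    stage <- "train/eval"
    spec <- build_model(input_shape_for(cfg$input_type))
    tc <- train_config(cfg$input_type, initial_lr = cfg$initial_lr,
                       decay_steps = cfg$decay_steps,
                       decay_rate = cfg$decay_rate,
                       max_steps = cfg$max_steps,
                       batch_size = cfg$batch_size,
                       seed = derive_seed(cfg$seed, 3L))
    reports <- list(); fits <- list()
    for (fold in folds) {
      tr <- prep$subject_ids %in% fold$train_subjects
      w0 <- init_cnn_weights(spec, seed = derive_seed(cfg$seed,
                                                      10L + fold$iteration))
      tc_it <- tc
      tc_it$seed <- derive_seed(cfg$seed, 20L + fold$iteration)
      fit <- train_model(w0, prep$x[, , , tr, drop = FALSE], y[tr], tc_it)
      rep <- evaluate_model(fit$weights, prep$x[, , , !tr, drop = FALSE],
                            y[!tr], operating_point = tc$operating_point)
      utils::write.csv(rep$roc_points,
                       file.path(out_dir, sprintf("roc_iter%d.csv",
                                                  fold$iteration)),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(step = seq_along(fit$loss),
                                  loss = fit$loss, lr = fit$lr),
                       file.path(out_dir, sprintf("train_log_iter%d.csv",
                                                  fold$iteration)),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(iteration = fold$iteration,
             per_class_accuracy = as.list(rep$per_class_accuracy),
             average_accuracy = rep$average_accuracy, auc = rep$auc,
             n_test_frames = rep$n),
        file.path(out_dir, sprintf("eval_iter%d.json", fold$iteration)),
        auto_unbox = TRUE, digits = NA)
      reports[[fold$iteration]] <- rep
      fits[[fold$iteration]] <- fit
    }

    stage <- "gradcam"
    test1 <- which(prep$subject_ids %in% folds[[1]]$test_subjects)
    n_cam <- min(cfg$n_gradcam, length(test1))
    cam_ids <- test1[seq_len(n_cam)]
    cam_fracs <- numeric(0)
    for (i in cam_ids) {
      img <- prep$x[, , , i]
      hm <- gradcam(fits[[1]]$weights, img)
      upsample_overlay(hm, img,
                       path = file.path(out_dir,
                                        sprintf("gradcam_frame%04d.png", i)))
      sc <- attention_fraction(hm, prep$masks[[i]]$sclera)
      cam_fracs <- c(cam_fracs, sc$mask_fraction)
    }

    stage <- "features"
    fm <- extract_features(fits[[1]]$weights, prep$x, labels = y,
                           subject_ids = prep$subject_ids)
    write_features_csv(fm, file.path(out_dir, "features.csv"))
    proj <- pca_project(fm)
    plot_feature_cloud(proj, fm$labels,
                       path = file.path(out_dir, "feature_cloud.png"))

    stage <- "knn-sigma"
    curve <- knn_sigma_curve(fm)
    write_knn_sigma_csv(curve, file.path(out_dir, "knn_sigma.csv"))

    stage <- "summary"
    summary <- list(
      config = unclass(cfg),
      per_iteration = lapply(reports, function(r)
        list(per_class_accuracy = as.list(r$per_class_accuracy),
             average_accuracy = r$average_accuracy, auc = r$auc,
             n_test_frames = r$n)),
      mean_auc = mean(vapply(reports, `[[`, 0, "auc")),
      mean_average_accuracy = mean(vapply(reports, `[[`, 0,
                                          "average_accuracy")),
      gradcam_sclera_fraction = as.list(cam_fracs),
      knn_sigma_summary_P = curve$summary_P,
      pca_eigenvalues = as.list(proj$eigenvalues)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
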