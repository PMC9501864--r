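#' Configuration for the end-to-end pipeline
#'
#' Bundles the per-stage settings. All randomness flows from `seed` through
#' named per-stage substreams, so a rerun with the same config is
#' reproducible. The defaults are the package's CPU-scale profile: small
#' images, a reduced-width network and a capped iteration count.
#'
#' @param n_images number of synthetic images to generate.
#' @param phantom a [phantom_config()].
#' @param train a [train_config()].
#' @param width network width multiplier.
#' @param finetune_iters length of a low-learning-rate fine-tuning phase
#'   run after the main schedule (0 disables it).
#' @param finetune_lr learning rate of the fine-tuning phase.
#' @param n_anchors number of anchors to estimate from the training boxes.
#' @param fractions train/validation/test split fractions.
#' @param conf_threshold,nms_iou inference settings.
#' @param iou_min evaluation IoU gate.
#' @param multipliers triage gate multipliers; `triage = FALSE` disables the
#'   triage stage.
#' @param triage run the triage stage.
#' @param write_images write the generated rasters as PNG files.
#' @param seed global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_images = 200,
                            phantom = phantom_config(image_size = 128),
                            train = train_config(epochs = 1000,
                                                 batch_size = 8,
                                                 warmup_iters = 100,
                                                 val_frequency = 50,
                                                 augment = FALSE,
                                                 max_iters = 1000),
                            width = 0.25, finetune_iters = 300,
                            finetune_lr = 1e-4, n_anchors = 6,
                            fractions = c(0.75, 0.10, 0.15),
                            conf_threshold = 0.5, nms_iou = 0.5,
                            iou_min = 0.5,
                            multipliers = c(0.5, 0.75, 1.0, 1.25, 1.5),
                            triage = TRUE, write_images = FALSE,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Named substream seeds derived from the global seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(synth = 101L, split = 211L, anchors = 307L, model = 401L,
               train = 503L, finetune = 601L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483629L
}

#' Run the full pipeline: generate, train, evaluate, triage
#'
#' Executes the stages in order -- synthetic dataset generation, train /
#' validation / test split, anchor estimation (training boxes only), model
#' training, inference on the held-out test split, detection evaluation and
#' triage scoring -- writing each stage's artifacts under `out_dir` together
#' with a manifest listing every file with its MD5 content hash. A stage
#' failure aborts with the stage name after removing that stage's partial
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param verbose log per-stage counts.
#' @return Invisibly, a list with the evaluation `summary`, `triage` results,
#'   training `history`, and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(...) if (verbose) message(sprintf(...))
  stage_files <- character(0)
  run_stage <- function(name, expr) {
    stage_files <<- character(0)
    tryCatch(expr, error = function(e) {
      suppressWarnings(file.remove(stage_files[file.exists(stage_files)]))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(path) {
    stage_files <<- c(stage_files, path)
    files <<- c(files, path)
    path
  }

  # --- synth ----------------------------------------------------------------
  dataset <- run_stage("synth", {
    imgs <- generate_dataset(config$n_images, config$phantom,
                             seed = stage_seed(config$seed, "synth"))
    names(imgs) <- sprintf("img%04d", seq_along(imgs))
    write_coco_annotations(imgs, emit(file.path(out_dir, "annotations.json")))
    write_boxes_csv(truth_table(imgs),
                    emit(file.path(out_dir, "annotations.csv")))
    if (config$write_images) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (nm in names(imgs))
        write_image_png(imgs[[nm]],
                        emit(file.path(img_dir, paste0(nm, ".png"))))
    }
    note("synth: %d images, %d boxes", length(imgs),
         nrow(truth_table(imgs)))
    imgs
  })

  # --- split / anchors / train ---------------------------------------------
  splits <- run_stage("split",
    split_dataset(dataset, config$fractions,
                  seed = stage_seed(config$seed, "split")))
  note("split: %d train / %d val / %d test", length(splits$train),
       length(splits$val), length(splits$test))

  anchors <- run_stage("anchors", {
    tb <- truth_table(splits$train)
    estimate_anchors(tb, k = min(config$n_anchors,
                                 nrow(unique(cbind(tb$w, tb$h)))),
                     seed = stage_seed(config$seed, "anchors"))
  })

  trained <- run_stage("train", {
    model <- build_model(anchors,
                         input_size = config$phantom$image_size,
                         n_classes = 4, width = config$width,
                         seed = stage_seed(config$seed, "model"))
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, "train")
    r <- train(model, splits$train, splits$val, cfg)
    if (config$finetune_iters > 0) {
      ft <- cfg
      ft$base_lr <- config$finetune_lr
      ft$warmup_iters <- 10
      ft$max_iters <- config$finetune_iters
      ft$seed <- stage_seed(config$seed, "finetune")
      r2 <- train(r$model, splits$train, splits$val, ft)
      r2$history$iteration <- r2$history$iteration + nrow(r$history)
      r <- list(model = r2$model,
                history = rbind(r$history, r2$history),
                best_val_loss = min(r$best_val_loss, r2$best_val_loss,
                                    na.rm = TRUE))
    }
    utils::write.csv(r$history,
                     emit(file.path(out_dir, "training_history.csv")),
                     row.names = FALSE)
    save_model(r$model, emit(file.path(out_dir, "checkpoint.rds")))
    note("train: %d iterations, final loss %.4f", nrow(r$history),
         r$history$loss[nrow(r$history)])
    r
  })

  # --- predict / evaluate ---------------------------------------------------
  evalr <- run_stage("evaluate", {
    dets <- predict_dataset(trained$model, splits$test,
                            config$conf_threshold, config$nms_iou)
    write_coco_detections(dets, emit(file.path(out_dir, "detections.json")))
    truths <- truth_table(splits$test)
    ev <- evaluate_detections(dets, truths, classes = coco_classes,
                              iou_min = config$iou_min)
    utils::write.csv(ev$summary,
                     emit(file.path(out_dir, "evaluation_report.csv")),
                     row.names = FALSE)
    jsonlite::write_json(ev$summary,
                         emit(file.path(out_dir, "evaluation_report.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    note("evaluate: %d detections on %d test images", nrow(dets),
         length(splits$test))
    list(ev = ev, dets = dets, truths = truths)
  })

  # --- triage ---------------------------------------------------------------
  triage_res <- NULL
  if (isTRUE(config$triage)) {
    triage_res <- run_stage("triage", {
      tr <- triage_images(evalr$dets, evalr$truths, config$multipliers)
      if (!is.null(tr$records))
        write_boxes_csv(tr$records,
                        emit(file.path(out_dir, "triage_records.csv")))
      s <- tr$summary
      jsonlite::write_json(
        list(n_images = s$n_images, mean_d_min = s$mean_d_min,
             reference_diameter = s$reference_diameter,
             feature_stats = s$feature_stats, flagged = s$flagged),
        emit(file.path(out_dir, "triage_summary.json")),
        auto_unbox = TRUE, digits = NA, na = "null")
      note("triage: %d of %d test images had all four classes predicted",
           s$n_images, length(splits$test))
      tr
    })
  }

  # --- manifest -------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config),
                                              c("phantom", "train"))],
                               auto_unbox = TRUE, force = TRUE)
  manifest <- c(
    sprintf("config_hash_md5: %s",
            md5_string(paste(cfg_json, config$seed))),
    sprintf("seed: %d", config$seed),
    sprintf("%s: %s", basename(files), tools::md5sum(files)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(summary = evalr$ev$summary, evaluation = evalr$ev,
                 triage = triage_res, history = trained$history,
                 files = c(files, file.path(out_dir, "manifest.txt"))))
}

md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
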