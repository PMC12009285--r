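#' Pipeline configuration
#'
#' Flat configuration of the full thermogram pipeline
#' (simulate/load -> preprocess -> segment -> extract -> fuse -> tune ->
#' evaluate). Construction is fail-fast: only the documented fields exist,
#' and [read_pipeline_config()] rejects unknown keys in a YAML/JSON document.
#'
#' @param out_dir run directory (created if missing).
#' @param seed master seed stamped into every artifact.
#' @param cohort_dir optional existing cohort directory containing
#'   `manifest.csv`; when `NULL` a synthetic cohort is generated under
#'   `out_dir/cohort`.
#' @param n_normal,n_abnormal synthetic cohort class counts.
#' @param image_size synthetic image size `c(H, W)`.
#' @param noise_sigma synthetic sensor-noise sd.
#' @param use_clahe,use_hist_eq,use_segmentation stage toggles; with
#'   segmentation off, extraction consumes the preprocessed images directly.
#' @param output_dim per-branch feature length.
#' @param branches feature branches to use (subset of `c("f1","f2","f3")`);
#'   fewer than three branches disables fusion-weight tuning and concatenates
#'   nothing — the single branch is used as-is.
#' @param single_head logical; train one classifier head instead of the
#'   three-head ensemble (the no-fusion ablation baseline).
#' @param tune logical; tune fusion weights + head hyperparameters with the
#'   hybrid optimizer (otherwise the space midpoint is used).
#' @param tune_population,tune_iterations optimizer budget for tuning.
#' @param threshold_population,threshold_iterations optimizer budget for
#'   per-image threshold search.
#' @param threshold_hot_range logical; restrict the threshold search to the
#'   clinical hot range `[200, 255]` (the default). After equalization spreads
#'   intensities over the full scale, a full-range Otsu split merely bisects
#'   the flattened histogram; the hot-range restriction is what isolates
#'   hyperthermic foci.
#' @param split train/validation/test fractions (sums to 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort_dir = NULL,
                            n_normal = 20L, n_abnormal = 20L,
                            image_size = c(64L, 64L), noise_sigma = 5,
                            use_clahe = TRUE, use_hist_eq = TRUE,
                            use_segmentation = TRUE, output_dim = 64L,
                            branches = c("f1", "f2", "f3"),
                            single_head = FALSE, tune = TRUE,
                            tune_population = 6L, tune_iterations = 5L,
                            threshold_population = 10L,
                            threshold_iterations = 10L,
                            threshold_hot_range = TRUE,
                            split = c(0.5, 0.25, 0.25)) {
  stopifnot(all(branches %in% c("f1", "f2", "f3")), length(branches) >= 1,
            length(split) == 3L, abs(sum(split) - 1) < 1e-8)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_dir = cohort_dir, n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma, use_clahe = use_clahe,
                 use_hist_eq = use_hist_eq,
                 use_segmentation = use_segmentation,
                 output_dim = as.integer(output_dim), branches = branches,
                 single_head = single_head, tune = tune,
                 tune_population = as.integer(tune_population),
                 tune_iterations = as.integer(tune_iterations),
                 threshold_population = as.integer(threshold_population),
                 threshold_iterations = as.integer(threshold_iterations),
                 threshold_hot_range = threshold_hot_range,
                 split = split),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are an error (fail-fast).
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0L) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, doc)
}

# md5 of the canonical JSON form of the config (stamped into artifacts)
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

# preprocess one image per the stage toggles
.preprocess_image <- function(img, config) {
  if (config$use_clahe) img <- clahe(img)
  if (config$use_hist_eq) img <- hist_equalize(img)
  img
}

#' Run the full pipeline
#'
#' Executes simulate/load -> preprocess -> segment -> extract -> fuse ->
#' tune/train -> evaluate on a cohort, writing all artifacts under
#' `config$out_dir`: the cohort (when simulated), predicted masks, feature
#' CSVs, the fitted model (JSON), `predictions.csv`, `metrics.csv` (columns
#' Accuracy, Recall, Specificity, Precision, FPR, FNR, NPV, FDR, F1-Score,
#' MCC), `segmentation_overlap.csv` (Dice/Jaccard vs ground truth when masks
#' exist), and `log.txt` stamped with the seed and config hash. Rerunning
#' with an identical configuration reproduces `metrics.csv` byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return list with `metrics` (tibble), `predictions`, `overlap`, `hp`,
#'   `weights`, `accuracy` (held-out test accuracy), `run_dir`, and
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  logf <- file.path(config$out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("thermofuse run\nseed: %d\nconfig_hash: %s\n",
              config$seed, hash), file = logf)

  # --- cohort ----------------------------------------------------------------
  cdir <- config$cohort_dir
  if (is.null(cdir)) {
    cdir <- file.path(config$out_dir, "cohort")
    generate_cohort(config$n_normal, config$n_abnormal, cdir,
                    seed = config$seed, size = config$image_size,
                    noise_sigma = config$noise_sigma)
    logline("stage simulate: %d normal + %d abnormal phantoms",
            config$n_normal, config$n_abnormal)
  }
  manifest <- tibble::as_tibble(utils::read.csv(file.path(cdir, "manifest.csv"),
                                               stringsAsFactors = FALSE))
  need <- c("image_path", "label")
  if (!all(need %in% names(manifest))) {
    stop("stage load: manifest missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "), call. = FALSE)
  }
  imgs <- lapply(manifest$image_path, function(p) read_gray(file.path(cdir, p)))
  labels <- factor(manifest$label)

  # --- preprocess ------------------------------------------------------------
  imgs <- lapply(imgs, .preprocess_image, config = config)
  logline("stage preprocess: clahe=%s hist_eq=%s", config$use_clahe,
          config$use_hist_eq)

  # --- segment ---------------------------------------------------------------
  masks <- NULL
  overlap <- NULL
  if (config$use_segmentation) {
    tcfg <- function(i) optimizer_config(
      population_size = config$threshold_population,
      max_iterations = config$threshold_iterations,
      seed = .derive_seed(config$seed, i))
    seg <- lapply(seq_along(imgs), function(i) {
      optimal_threshold(imgs[[i]], fitness = "otsu", config = tcfg(i),
                        hot_range = config$threshold_hot_range)
    })
    masks <- lapply(seg, `[[`, "mask")
    mdir <- file.path(config$out_dir, "pred_masks")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(masks)) {
      write_mask(masks[[i]], file.path(mdir, sprintf("mask_%03d.png", i)))
    }
    if ("mask_path" %in% names(manifest)) {
      ov <- lapply(seq_along(masks), function(i) {
        mask_overlap(masks[[i]], read_mask(file.path(cdir, manifest$mask_path[i])))
      })
      overlap <- do.call(rbind, ov)
      overlap <- tibble::add_column(overlap, image = manifest$image_path,
                                    threshold = vapply(seg, `[[`, numeric(1),
                                                       "threshold"),
                                    .before = 1)
      utils::write.csv(overlap, file.path(config$out_dir,
                                          "segmentation_overlap.csv"),
                       row.names = FALSE)
    }
    logline("stage segment: otsu fitness, %d images", length(imgs))
  }

  # --- extract ---------------------------------------------------------------
  feats <- extract_feature_matrix(imgs, masks, output_dim = config$output_dim)
  for (b in config$branches) {
    fm <- feats[[b]]
    colnames(fm) <- sprintf("%s_%03d", b, seq_len(ncol(fm)))
    utils::write.csv(fm, file.path(config$out_dir,
                                   sprintf("features_%s.csv", b)),
                     row.names = FALSE)
  }
  logline("stage extract: %d x %d per branch", nrow(feats$f1),
          ncol(feats$f1))

  # --- split + tune/train ----------------------------------------------------
  sp <- stratified_split(labels, config$split, seed = config$seed)
  train <- sp[[1]]; val <- sp[[2]]; test <- sp[[3]]
  ocfg <- optimizer_config(population_size = config$tune_population,
                           max_iterations = config$tune_iterations,
                           max_seeds = 5L, seed = config$seed)
  if (length(config$branches) == 3L) {
    if (config$tune) {
      fit <- optimize_hyperparameters(feats$f1, feats$f2, feats$f3, labels,
                                      train, val, config = ocfg)
      hp <- fit$hp
    } else {
      space <- hp_space()
      g <- c(0.5, 0.5, 0.5, mean(space$epochs), mean(space$hidden), 1)
      hp <- .decode_hp(g, space)
    }
    SF <- fuse(feats$f1, feats$f2, feats$f3, hp$weights)
  } else {
    space <- hp_space()
    g <- c(1, 0, 0, mean(space$epochs), mean(space$hidden), 1)
    hp <- .decode_hp(g, space)
    SF <- feats[[config$branches[1]]]
  }
  fit_set <- sort(c(train, val))  # refit on train + validation
  heads <- if (config$single_head) {
    list(head = .fit_mlp(SF[fit_set, , drop = FALSE], labels[fit_set],
                         hidden = hp$hidden, activation = hp$activation,
                         epochs = hp$epochs, seed = config$seed))
  } else {
    fit_heads(SF[fit_set, , drop = FALSE], labels[fit_set],
              hidden = hp$hidden, activation = hp$activation,
              epochs = hp$epochs, seed = config$seed)
  }
  logline("stage train: hidden=%d activation=%s epochs=%d tuned=%s",
          hp$hidden, hp$activation, hp$epochs, config$tune)

  # --- evaluate --------------------------------------------------------------
  pred <- predict_ensemble(heads, SF[test, , drop = FALSE])
  predictions <- tibble::tibble(image = manifest$image_path[test],
                                truth = as.character(labels[test]),
                                predicted = pred$class)
  utils::write.csv(predictions, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  cm <- confusion(pred$class, labels[test], positive = "abnormal")
  rep <- metric_report(cm)
  metrics <- stats::setNames(
    rep[, c("accuracy", "sensitivity", "specificity", "precision", "fpr",
            "fnr", "npv", "fdr", "f1", "mcc")],
    c("Accuracy", "Recall", "Specificity", "Precision", "FPR", "FNR", "NPV",
      "FDR", "F1-Score", "MCC"))
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  model <- list(seed = config$seed, config_hash = hash, hp = hp,
                weights = hp$weights, n_heads = length(heads))
  writeLines(jsonlite::toJSON(model, auto_unbox = TRUE, digits = NA),
             file.path(config$out_dir, "model.json"))
  logline("stage evaluate: test accuracy %.3f", rep$accuracy)

  list(metrics = metrics, predictions = predictions, overlap = overlap,
       hp = hp, weights = hp$weights, accuracy = rep$accuracy,
       run_dir = config$out_dir, config_hash = hash)
}
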