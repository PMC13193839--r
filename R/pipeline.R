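#' End-to-end pipeline configuration
#'
#' Bundles the stage toggles and every stage's parameters. Input data come
#' either from a directory of class folders (`data_root`) or from the phantom
#' generator (`phantom_n_per_class`). Nodule masking consumes the segmented
#' image, so `use_nodule_masking` requires `use_clahe_segmentation`.
#'
#' @param data_root directory with `Benign/Malignant/Normal` folders, or
#'   `NULL` to use phantoms.
#' @param phantom_n_per_class phantoms per class when `data_root` is `NULL`.
#' @param phantom a [phantom_spec()].
#' @param use_clahe_segmentation,use_nodule_masking,use_bigru_head stage
#'   toggles (all on by default; the first two reproduce the preprocessing
#'   stack, the third selects the recurrent head over the dense baseline).
#' @param seg a [segmentation_params()].
#' @param nodule a [nodule_mask_params()].
#' @param augment an [augment_config()], or `NULL` for no augmentation.
#' @param test_per_class held-out images per class.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param seed run seed; seeds for data generation, split, weight
#'   initialisation and training are derived from it.
#' @param out_dir run directory (created by [run_pipeline()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data_root = NULL,
                            phantom_n_per_class = 60L,
                            phantom = phantom_spec(),
                            use_clahe_segmentation = TRUE,
                            use_nodule_masking = TRUE,
                            use_bigru_head = TRUE,
                            seg = segmentation_params(),
                            nodule = nodule_mask_params(),
                            augment = augment_config(),
                            test_per_class = 15L,
                            model = toy_model_config(),
                            train = train_config(learning_rate = 1e-3,
                                                 freeze_policy = "none"),
                            seed = 1L,
                            out_dir = tempfile("lungct_run_")) {
  cfg <- list(data_root = data_root,
              phantom_n_per_class = as.integer(phantom_n_per_class),
              phantom = phantom,
              use_clahe_segmentation = isTRUE(use_clahe_segmentation),
              use_nodule_masking = isTRUE(use_nodule_masking),
              use_bigru_head = isTRUE(use_bigru_head),
              seg = seg, nodule = nodule, augment = augment,
              test_per_class = as.integer(test_per_class),
              model = model, train = train,
              seed = as.integer(seed), out_dir = out_dir)
  assert_that(!(cfg$use_nodule_masking && !cfg$use_clahe_segmentation),
              "use_nodule_masking requires use_clahe_segmentation (the candidate mask is taken on the segmented image)")
  class(cfg) <- "pipeline_config"
  cfg
}

# One image through the preprocessing stack: resize 512, optional
# segmentation, optional nodule masking, then the 224 backbone-size
# grayscale plane.
preprocess_image <- function(image, config) {
  img <- resize_to(image, 512L, 512L, "bilinear")
  if (config$use_clahe_segmentation) {
    seg <- suppressWarnings(segment_lungs(img, config$seg))
    img <- seg$image
    if (config$use_nodule_masking) {
      cm <- candidate_mask(img, seg$mask, config$nodule)
      img <- apply_candidate_mask(img, cm)
    }
  }
  resize_to(img, 224L, 224L, "bilinear")
}

# Resolve the configured data source into images + labels (in memory).
resolve_inputs <- function(config) {
  if (!is.null(config$data_root)) {
    manifest <- build_manifest(config$data_root)
    images <- lapply(manifest$path, load_grayscale)
    list(images = images, labels = manifest$label, ref = manifest$path)
  } else {
    recs <- generate_phantom_set(config$phantom, config$phantom_n_per_class,
                                 derive_seed(config$seed, 1L))
    list(images = lapply(recs, `[[`, "image"),
         labels = vapply(recs, `[[`, character(1), "label"),
         ref = sprintf("phantom_%03d", seq_along(recs)))
  }
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Run the full pipeline
#'
#' Load (or generate) -> resize 512 -> segment -> nodule-mask -> backbone
#' input -> balanced split -> train -> evaluate, honouring the stage toggles.
#' The run directory receives the resolved configuration (`config.yaml`),
#' split manifest (`manifest.csv`), training history (`history.csv`), the
#' evaluation report (`report.json`, `report.txt`) and returns everything
#' in memory as well. All randomness derives from `config$seed`, so a
#' repeated run writes byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return invisible list: `run_dir`, `cm`, `metrics`, `report`, `history`,
#'   `fit`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- resolve_inputs(config)
  processed <- lapply(inputs$images, preprocess_image, config = config)

  manifest <- tibble::tibble(path = inputs$ref, label = inputs$labels,
                             split = "unsplit")
  sp <- split_manifest(manifest, config$test_per_class,
                       seed = derive_seed(config$seed, 2L))
  idx_train <- match(sp$train$path, manifest$path)
  idx_test <- match(sp$test$path, manifest$path)
  manifest$split[idx_train] <- "train"
  manifest$split[idx_test] <- "test"
  write_manifest(manifest, file.path(config$out_dir, "manifest.csv"))

  mcfg <- config$model
  mcfg$use_bigru_head <- config$use_bigru_head
  model <- build_model(mcfg, seed = derive_seed(config$seed, 3L))
  tcfg <- config$train
  tcfg$seed <- derive_seed(config$seed, 4L)
  fit <- train_model(model,
                     processed[idx_train], manifest$label[idx_train],
                     processed[idx_test], manifest$label[idx_test],
                     tcfg, aug = config$augment)
  utils::write.csv(fit$history, file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)

  pred <- predict(fit$model, processed[idx_test])
  cm <- confusion(manifest$label[idx_test], pred$label)
  metrics <- compute_metrics(cm)
  report <- render_report(metrics, cm,
                          json_path = file.path(config$out_dir, "report.json"))
  writeLines(report$text, file.path(config$out_dir, "report.txt"))
  yaml::write_yaml(strip_classes(unclass(config)),
                   file.path(config$out_dir, "config.yaml"))
  invisible(list(run_dir = config$out_dir, cm = cm, metrics = metrics,
                 report = report, history = fit$history, fit = fit,
                 manifest = manifest))
}

#' Staged ablation of the pipeline
#'
#' Three cumulative runs sharing identical data, split and seeds:
#' segmentation with a dense head, plus nodule masking, plus the BiGRU head.
#' Preprocessing variants are computed once and reused, so the three rows
#' differ only in the toggled stage. Precision and recall are macro-averaged
#' over the three classes.
#'
#' @param config a [pipeline_config()] (its toggles are overridden per row).
#' @param include_raw_baseline also run a stage-0 row with no segmentation.
#' @return tibble with columns `stage`, `accuracy`, `precision`, `recall`.
#' @export
run_ablation <- function(config = pipeline_config(), include_raw_baseline = FALSE) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  inputs <- resolve_inputs(config)

  variants <- list()
  if (include_raw_baseline) {
    variants[["Baseline (raw)"]] <- list(seg = FALSE, mask = FALSE, bigru = FALSE)
  }
  variants[["Baseline + Seg."]] <- list(seg = TRUE, mask = FALSE, bigru = FALSE)
  variants[["+ Masking"]] <- list(seg = TRUE, mask = TRUE, bigru = FALSE)
  variants[["+ BiGRU (Final)"]] <- list(seg = TRUE, mask = TRUE, bigru = TRUE)

  # preprocess each distinct preprocessing variant once
  need <- unique(vapply(variants, function(v) paste(v$seg, v$mask), character(1)))
  pp <- list()
  for (key in need) {
    flags <- strsplit(key, " ")[[1]] == "TRUE"
    vcfg <- config
    vcfg$use_clahe_segmentation <- flags[1]
    vcfg$use_nodule_masking <- flags[2]
    pp[[key]] <- lapply(inputs$images, preprocess_image, config = vcfg)
  }

  manifest <- tibble::tibble(path = inputs$ref, label = inputs$labels,
                             split = "unsplit")
  sp <- split_manifest(manifest, config$test_per_class,
                       seed = derive_seed(config$seed, 2L))
  idx_train <- match(sp$train$path, manifest$path)
  idx_test <- match(sp$test$path, manifest$path)

  rows <- list()
  for (stage in names(variants)) {
    v <- variants[[stage]]
    processed <- pp[[paste(v$seg, v$mask)]]
    mcfg <- config$model
    mcfg$use_bigru_head <- v$bigru
    model <- build_model(mcfg, seed = derive_seed(config$seed, 3L))
    tcfg <- config$train
    tcfg$seed <- derive_seed(config$seed, 4L)
    fit <- train_model(model,
                       processed[idx_train], manifest$label[idx_train],
                       processed[idx_test], manifest$label[idx_test],
                       tcfg, aug = config$augment)
    pred <- predict(fit$model, processed[idx_test])
    cm <- confusion(manifest$label[idx_test], pred$label)
    m <- compute_metrics(cm)
    rows[[stage]] <- tibble::tibble(stage = stage,
                                    accuracy = m$accuracy,
                                    precision = mean(m$per_class$precision),
                                    recall = mean(m$per_class$recall))
  }
  do.call(rbind, rows)
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' blocks `phantom`, `seg`, `nodule`, `augment`, `model`, `train` are passed
#' to the corresponding constructors, so defaults apply to anything omitted.
#' `augment: off` disables augmentation.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- c("phantom", "seg", "nodule", "augment", "model", "train")
  args <- y[setdiff(names(y), blocks)]
  build <- function(ctor, block) if (is.null(block)) NULL else do.call(ctor, block)
  if (!is.null(y[["phantom"]])) args$phantom <- build(phantom_spec, y[["phantom"]])
  if (!is.null(y[["seg"]])) args$seg <- build(segmentation_params, y[["seg"]])
  if (!is.null(y[["nodule"]])) args$nodule <- build(nodule_mask_params, y[["nodule"]])
  if (!is.null(y[["augment"]])) {
    if (identical(y[["augment"]], "off")) {
      args["augment"] <- list(NULL)
    } else {
      args$augment <- build(augment_config, y[["augment"]])
    }
  }
  if (!is.null(y[["model"]])) args$model <- build(model_config, y[["model"]])
  if (!is.null(y[["train"]])) args$train <- build(train_config, y[["train"]])
  do.call(pipeline_config, args)
}
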