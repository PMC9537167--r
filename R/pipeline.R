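#' @title End-to-end pipeline helpers
#' @description Convenience wrappers chaining the stages: meta-level
#'   train/test division, leakage-safe resampling (SMOTE strictly on the
#'   training portion), detector training and held-out evaluation; and
#'   the full synthetic recovery pipeline (fingerprint sets -> model
#'   grid -> meta arrays -> detector).
#' @name pipeline
NULL

#' Split a meta-array dataset 70:30 (stratified)
#'
#' @param data An `array_dataset`.
#' @param train_fraction Default 0.70.
#' @param seed Integer seed.
#' @return List `train`, `test` (both `array_dataset`).
#' @export
split_arrays <- function(data, train_fraction = 0.70, seed = 1) {
  stopifnot(inherits(data, "array_dataset"))
  if (any(data$synthetic))
    stop("split before oversampling: dataset already contains ",
         "synthetic arrays")
  y <- data$class_labels
  train_idx <- with_seed(seed, {
    sort(unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, round(length(idx) * train_fraction))),
      use.names = FALSE))
  })
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = subset_arrays(data, train_idx),
       test = subset_arrays(data, test_idx))
}

#' Train and evaluate a detector under one sampling regime
#'
#' Divides the native arrays 70:30 (stratified), applies the requested
#' sampling regime to the training portion only (the held-out portion
#' stays native, so no synthetic array can leak into evaluation),
#' trains the network and evaluates on the held-out portion.
#'
#' @param arrays Native (`Model01`) `array_dataset`.
#' @param shape Array layout for the network (default `"50x4"`).
#' @param sampling_model `"Model01"`..`"Model04"`.
#' @param kind `"CNN"` or `"MLP"` (equal-depth baseline).
#' @param config Optional [cnn_config()]; default built from `shape`
#'   and `seed`.
#' @param train_fraction,seed Meta-split parameters.
#' @param k_neighbors SMOTE neighbourhood (default 5).
#' @return List: `model`, `trace`, `stopped_epoch`, `evaluation` (from
#'   [evaluate_detector()]), `train`, `test`.
#' @export
train_detector <- function(arrays, shape = "50x4",
                           sampling_model = "Model01", kind = "CNN",
                           config = NULL, train_fraction = 0.70,
                           seed = 1, k_neighbors = 5) {
  kind <- match.arg(kind, c("CNN", "MLP"))
  if (is.null(config)) config <- cnn_config(input_shape = shape,
                                            seed = seed)
  halves <- split_arrays(arrays, train_fraction, seed)
  train <- sampling_regime(halves$train, sampling_model, k_neighbors,
                           seed)
  train$shape <- shape
  net <- if (kind == "CNN") build_cnn(config) else
    build_mlp_baseline(config)
  fit <- nn_train(net, train, config)
  list(model = fit$model, trace = fit$trace,
       stopped_epoch = fit$stopped_epoch,
       evaluation = evaluate_detector(fit$model, halves$test),
       train = train, test = halves$test)
}

#' Run the full synthetic recovery pipeline
#'
#' Generates the per-target planted-signal fingerprint sets, trains the
#' model grid, scores a synthetic meta stage with it, and trains the
#' detector on the resulting arrays.
#'
#' @param spec A [synthetic_spec()].
#' @param seeds Grid seed indices (default 1:3 for a reduced grid).
#' @param algorithms Algorithms to train (default all four).
#' @param shape,sampling_model,detector_seed Detector settings.
#' @return List: `sets`, `grid`, `arrays`, `selection` (best models),
#'   `detector` (from [train_detector()]).
#' @export
run_synthetic_pipeline <- function(spec = synthetic_spec(),
                                   seeds = 1:3,
                                   algorithms = DTI_ALGORITHMS,
                                   shape = "50x4",
                                   sampling_model = "Model03",
                                   detector_seed = 1) {
  sets <- gen_dti_dataset(spec)
  specs <- grid_specs(targets = CHOLINERGIC_TARGETS,
                      algorithms = algorithms, seeds = seeds)
  grid <- train_grid(sets, specs)
  arrays <- gen_meta_stage(spec, grid = grid)
  detector <- train_detector(arrays, shape = shape,
                             sampling_model = sampling_model,
                             seed = detector_seed)
  list(sets = sets, grid = grid, arrays = arrays,
       selection = select_best(grid), detector = detector)
}

#' Held-out AUC of base models against the clean planted labels
#'
#' Signal-recovery view of grid quality on synthetic data: for every
#' (target, algorithm) the mean over seeds of the held-out ROC-AUC
#' computed against the clean (pre-noise) labels that the generator
#' attached to each set.
#'
#' @param grid A `base_model_grid` trained on [gen_dti_dataset()]
#'   output.
#' @return Data.frame: target, algorithm, auc_clean (mean over seeds).
#' @export
clean_label_auc_table <- function(grid) {
  rows <- list()
  for (t in grid$targets) for (a in grid$algorithms) {
    models <- Filter(function(e)
      e$spec$target == t && e$spec$algorithm == a, grid$entries)
    if (!length(models)) next
    aucs <- vapply(models, function(e) {
      yc <- e$test_labels_clean
      if (is.null(yc)) return(NA_real_)
      roc_auc(e$test_scores, yc)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      target = t, algorithm = a, auc_clean = mean(aucs))
  }
  do.call(rbind, rows)
}
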