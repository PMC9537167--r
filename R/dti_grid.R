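#' @title The 5 x 4 x 10 grid of DTI classifiers
#' @description Training and validation of the grid of binary
#'   drug-target-interaction classifiers: five cholinergic targets, four
#'   algorithms, ten seeds (200 models at the defaults). Each seed
#'   controls its own stratified 70:30 train/test division and any
#'   stochastic learner internals; models are selected per target by
#'   ensemble-AUC, the mean of seed-wise held-out ROC-AUCs.
#' @name dti_grid
NULL

#' Train/test split specification
#'
#' @param train_fraction Fraction of compounds in the training portion
#'   (default 0.70 for the 70:30 division).
#' @param stratified Preserve class proportions in both portions.
#' @param seed Integer seed making the partition reproducible.
#' @param cv_folds Folds for k-fold cross-validation (default 10).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, stratified = TRUE,
                       seed = 1, cv_folds = 10) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 stratified = stratified, seed = as.integer(seed),
                 cv_folds = as.integer(cv_folds)),
            class = "split_spec")
}

#' Stratified train/test division
#'
#' @param set A `labeled_fp_set`.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test` (both `labeled_fp_set`)
#'   and the index vectors `train_idx`, `test_idx`.
#' @export
split_set <- function(set, spec = split_spec()) {
  stopifnot(inherits(set, "labeled_fp_set"))
  y <- set$y
  if (spec$stratified && any(table(factor(y, levels = 0:1)) < 2))
    stop("stratification error: each class needs at least 2 members")
  train_idx <- with_seed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(split(seq_along(y), y), function(idx) {
        n_tr <- round(length(idx) * spec$train_fraction)
        sample(idx, n_tr)
      }), use.names = FALSE)
    } else sample(seq_along(y), round(length(y) * spec$train_fraction))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  subset_fp <- function(i) {
    out <- suppressWarnings(labeled_fp_set(
      set$compound_ids[i], set$x[i, , drop = FALSE], y[i], set$config))
    yc <- attr(set, "y_clean")
    if (!is.null(yc)) attr(out, "y_clean") <- yc[i]
    out
  }
  list(train = subset_fp(train_idx), test = subset_fp(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' k-fold cross-validation of one model specification
#'
#' Partitions the set into k folds (stratified), each fold validated
#' exactly once by a model trained on the remaining k-1 folds.
#'
#' @param set A `labeled_fp_set` (typically the training portion).
#' @param algorithm Base algorithm name.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and learner internals.
#' @param hyperparameters Passed to [fit_base_model()].
#' @return List with `folds` (per-fold `eval_report`s), `summary`
#'   (data.frame of mean and sd per metric) and `assignment` (fold id per
#'   compound).
#' @export
cross_validate <- function(set, algorithm = "RF", k = 10, seed = 1,
                           hyperparameters = list()) {
  y <- set$y; n <- length(y)
  if (k > n) stop("k = ", k, " exceeds n = ", n)
  if (k > min(table(factor(y, levels = 0:1))))
    stop("k exceeds the minority-class count; folds would lose a class")
  assignment <- with_seed(seed, {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
  reports <- lapply(seq_len(k), function(f) {
    hold <- assignment == f
    mod <- fit_base_model(set$x[!hold, , drop = FALSE], y[!hold],
                          algorithm, seed = seed,
                          hyperparameters = hyperparameters)
    scores <- predict(mod, set$x[hold, , drop = FALSE])
    if (length(unique(y[hold])) < 2)
      warning("fold ", f, " is single-class; ranking metrics undefined")
    evaluate_scores(scores, y[hold])
  })
  metrics <- c("accuracy", "precision", "recall", "tnr", "f1", "mcc",
               "auc_balanced", "auc_roc", "aupr")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) {
      v <- r[[m]]; if (is.null(v)) NA_real_ else v
    }, numeric(1)))
  summary <- data.frame(
    metric = metrics,
    mean = apply(vals, 2, mean, na.rm = TRUE),
    sd = apply(vals, 2, stats::sd, na.rm = TRUE), row.names = NULL)
  list(folds = reports, summary = summary, assignment = assignment)
}

#' Base-model grid specification
#'
#' One entry of the (target, algorithm, seed) cross-product.
#'
#' @param target One of [CHOLINERGIC_TARGETS].
#' @param algorithm One of [DTI_ALGORITHMS].
#' @param seed Integer seed index (the paper's S1..S10).
#' @param fingerprint An [fp_config()].
#' @param hyperparameters Named list of overrides.
#' @return An object of class `base_model_spec`.
#' @export
base_model_spec <- function(target, algorithm, seed,
                            fingerprint = fp_config(),
                            hyperparameters = list()) {
  target <- match.arg(target, CHOLINERGIC_TARGETS)
  algorithm <- match.arg(algorithm, DTI_ALGORITHMS)
  structure(list(target = target, algorithm = algorithm,
                 seed = as.integer(seed), fingerprint = fingerprint,
                 hyperparameters = hyperparameters),
            class = "base_model_spec")
}

#' Full grid of model specifications
#'
#' @param targets,algorithms Subsets of the canonical lists (defaults:
#'   all five targets, all four algorithms).
#' @param seeds Integer vector of seed indices (default 1:10).
#' @inheritParams base_model_spec
#' @return List of `base_model_spec`, length
#'   `|targets| * |algorithms| * |seeds|` (200 at the defaults), ordered
#'   canonically: target slowest, then seed, then algorithm.
#' @export
grid_specs <- function(targets = CHOLINERGIC_TARGETS,
                       algorithms = DTI_ALGORITHMS, seeds = 1:10,
                       fingerprint = fp_config(),
                       hyperparameters = list()) {
  specs <- list()
  for (t in targets) for (s in seeds) for (a in algorithms)
    specs[[length(specs) + 1L]] <-
      base_model_spec(t, a, s, fingerprint, hyperparameters)
  specs
}

#' Train the model grid
#'
#' Fits one classifier per specification. The seed of a spec determines
#' the stratified 70:30 division of its target's data (shared by all
#' algorithms at that seed) and the learner's stochastic internals. Test
#' metrics are computed only on the held-out portion.
#'
#' @param sets Named list of `labeled_fp_set`, one per target.
#' @param specs List of [base_model_spec()] (default: the full grid over
#'   the targets present in `sets`).
#' @param train_fraction Train fraction of the division (default 0.70).
#' @param cv_folds If `> 0`, additionally run k-fold cross-validation on
#'   each training portion (costly; default 0 = skip).
#' @param verbose Print one line per trained model.
#' @return A `base_model_grid`: list of trained entries plus the grid
#'   axes. Each entry carries `spec`, `model`, `train_report`,
#'   `test_report`, `cv` (or NULL), and the held-out indices. A training
#'   failure aborts only that entry (recorded in `failed`).
#' @export
train_grid <- function(sets, specs = NULL, train_fraction = 0.70,
                       cv_folds = 0, verbose = FALSE) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  if (is.null(specs)) specs <- grid_specs(targets = names(sets))
  targets <- unique(vapply(specs, `[[`, character(1), "target"))
  missing_t <- setdiff(targets, names(sets))
  if (length(missing_t))
    stop("no data for target(s): ", paste(missing_t, collapse = ", "))
  # one split per (target, seed), shared across algorithms
  splits <- new.env(parent = emptyenv())
  get_split <- function(target, seed) {
    key <- paste(target, seed)
    if (is.null(splits[[key]]))
      splits[[key]] <- split_set(sets[[target]],
                                 split_spec(train_fraction, TRUE, seed))
    splits[[key]]
  }
  entries <- list(); failed <- list()
  for (spec in specs) {
    sp <- get_split(spec$target, spec$seed)
    entry <- tryCatch({
      model <- fit_base_model(sp$train$x, sp$train$y, spec$algorithm,
                              seed = spec$seed,
                              hyperparameters = spec$hyperparameters)
      tr_scores <- predict(model, sp$train$x)
      te_scores <- predict(model, sp$test$x)
      cv <- if (cv_folds > 0)
        cross_validate(sp$train, spec$algorithm, cv_folds, spec$seed,
                       spec$hyperparameters) else NULL
      e <- list(spec = spec, model = model,
                train_report = evaluate_scores(tr_scores, sp$train$y),
                test_report = evaluate_scores(te_scores, sp$test$y),
                cv = cv, test_idx = sp$test_idx,
                test_scores = te_scores, test_labels = sp$test$y,
                test_labels_clean = attr(sp$test, "y_clean"))
      if (verbose)
        message(sprintf("%s %s S%d: test AUC %.3f", spec$target,
                        spec$algorithm, spec$seed,
                        e$test_report$auc_roc))
      e
    }, error = function(err) {
      warning(sprintf("training failed for %s/%s/S%d: %s", spec$target,
                      spec$algorithm, spec$seed, conditionMessage(err)))
      NULL
    })
    if (is.null(entry)) failed[[length(failed) + 1L]] <- spec
    else entries[[length(entries) + 1L]] <- entry
  }
  structure(list(entries = entries, failed = failed,
                 targets = targets,
                 algorithms = unique(vapply(specs, `[[`, character(1),
                                            "algorithm")),
                 seeds = sort(unique(vapply(specs, `[[`, integer(1),
                                            "seed"))),
                 fingerprint = specs[[1]]$fingerprint),
            class = "base_model_grid")
}

#' @export
print.base_model_grid <- function(x, ...) {
  cat(sprintf(
    "<base_model_grid> %d models: %d targets x %d algorithms x %d seeds%s\n",
    length(x$entries), length(x$targets), length(x$algorithms),
    length(x$seeds),
    if (length(x$failed)) sprintf(" (%d failed)", length(x$failed))
    else ""))
  invisible(x)
}

grid_entry <- function(grid, target, algorithm, seed) {
  for (e in grid$entries)
    if (e$spec$target == target && e$spec$algorithm == algorithm &&
        e$spec$seed == seed) return(e)
  NULL
}

#' Ensemble-AUC of a (target, algorithm) model family
#'
#' Seed-aggregated AUC used for best-model selection. Default
#' (`"mean_seed"`): every seed's model scores its own held-out set and
#' the ten ROC-AUCs are averaged. Alternative (`"averaged_prob"`): the
#' seed models' probabilities are averaged on one common evaluation set
#' and a single AUC of the averaged score is returned.
#'
#' @param models List of trained grid entries sharing target and
#'   algorithm (differing in seed).
#' @param method `"mean_seed"` or `"averaged_prob"`.
#' @param newdata,labels Evaluation set for `"averaged_prob"`.
#' @return A single AUC value.
#' @export
ensemble_auc <- function(models, method = c("mean_seed",
                                            "averaged_prob"),
                         newdata = NULL, labels = NULL) {
  method <- match.arg(method)
  stopifnot(length(models) >= 1)
  ta <- unique(t(vapply(models, function(e)
    c(e$spec$target, e$spec$algorithm), character(2))))
  if (nrow(ta) > 1)
    stop("models must share target and algorithm")
  if (length(models) < 2)
    warning("fewer than 2 seeds; ensemble-AUC reduces to a plain AUC")
  if (method == "mean_seed") {
    mean(vapply(models, function(e)
      roc_auc(e$test_scores, e$test_labels), numeric(1)))
  } else {
    if (is.null(newdata) || is.null(labels))
      stop("averaged_prob needs a common evaluation set")
    scores <- rowMeans(vapply(models, function(e)
      predict(e$model, newdata), numeric(nrow(newdata))))
    roc_auc(scores, labels)
  }
}

#' Ensemble-AUC table over the whole grid
#'
#' @param grid A `base_model_grid`.
#' @inheritParams ensemble_auc
#' @return Data.frame: target, algorithm, ensemble_auc, n_seeds.
#' @export
ensemble_auc_table <- function(grid, method = "mean_seed") {
  rows <- list()
  for (t in grid$targets) for (a in grid$algorithms) {
    models <- Filter(function(e)
      e$spec$target == t && e$spec$algorithm == a, grid$entries)
    if (!length(models)) next
    rows[[length(rows) + 1L]] <- data.frame(
      target = t, algorithm = a,
      ensemble_auc = suppressWarnings(ensemble_auc(models, method)),
      n_seeds = length(models))
  }
  do.call(rbind, rows)
}

#' Select best models by ensemble-AUC
#'
#' Per (target, algorithm) the best seed is the arg-max of held-out
#' ROC-AUC; per target the best algorithm is the arg-max of
#' ensemble-AUC. Ties break by higher held-out MCC, then lower seed
#' index (respectively earlier algorithm in the canonical order).
#'
#' @param grid A `base_model_grid`.
#' @return Data.frame with one row per target: `target`, `algorithm`,
#'   `seed`, `ensemble_auc`, `test_auc`, `test_mcc`.
#' @export
select_best <- function(grid) {
  ens <- ensemble_auc_table(grid)
  rows <- list()
  for (t in grid$targets) {
    sub <- ens[ens$target == t, , drop = FALSE]
    # tie-break among algorithms sharing the max ensemble-AUC
    top <- sub[abs(sub$ensemble_auc - max(sub$ensemble_auc)) < 1e-12, ,
               drop = FALSE]
    pick_model <- function(a) {
      models <- Filter(function(e)
        e$spec$target == t && e$spec$algorithm == a, grid$entries)
      auc <- vapply(models, function(e)
        roc_auc(e$test_scores, e$test_labels), numeric(1))
      mcc <- vapply(models, function(e) {
        v <- e$test_report$mcc; if (is.na(v)) -Inf else v
      }, numeric(1))
      seed <- vapply(models, function(e) e$spec$seed, integer(1))
      ord <- order(-auc, -mcc, seed)
      list(entry = models[[ord[1]]], auc = auc[ord[1]],
           mcc = mcc[ord[1]])
    }
    cands <- lapply(top$algorithm, pick_model)
    mccs <- vapply(cands, `[[`, numeric(1), "mcc")
    alg_rank <- match(top$algorithm, DTI_ALGORITHMS)
    sel <- order(-mccs, alg_rank)[1]
    e <- cands[[sel]]$entry
    rows[[length(rows) + 1L]] <- data.frame(
      target = t, algorithm = e$spec$algorithm, seed = e$spec$seed,
      ensemble_auc = top$ensemble_auc[sel], test_auc = cands[[sel]]$auc,
      test_mcc = cands[[sel]]$mcc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grid manifest
#'
#' Serializable description of a trained grid: axes, fingerprint
#' configuration, slot-order version and per-model metrics. The meta
#' stage consumes the manifest plus the score functions.
#'
#' @param grid A `base_model_grid`.
#' @return A list (JSON-ready via `jsonlite::toJSON`).
#' @export
grid_manifest <- function(grid) {
  list(targets = grid$targets, algorithms = grid$algorithms,
       seeds = grid$seeds,
       fingerprint = if (is.null(grid$fingerprint)) NULL else
         unclass(grid$fingerprint),
       slot_order_version = slot_order_version(),
       models = lapply(grid$entries, function(e) list(
         target = e$spec$target, algorithm = e$spec$algorithm,
         seed = e$spec$seed,
         test_auc = roc_auc(e$test_scores, e$test_labels),
         test_mcc = e$test_report$mcc,
         test_accuracy = e$test_report$accuracy)))
}

#' Persist a trained grid
#'
#' Writes one model file per entry plus a JSON manifest.
#'
#' @param grid A `base_model_grid`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(grid_manifest(grid),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (e in grid$entries)
    saveRDS(e, file.path(dir, sprintf("model_%s_%s_S%02d.rds",
                                      e$spec$target, e$spec$algorithm,
                                      e$spec$seed)))
  invisible(dir)
}

#' Load a persisted grid
#'
#' @param dir Directory written by [save_grid()].
#' @return A `base_model_grid`.
#' @export
load_grid <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$slot_order_version, slot_order_version()))
    stop("slot-order version mismatch; persisted grid is invalid")
  files <- sort(list.files(dir, pattern = "^model_.*\\.rds$",
                           full.names = TRUE))
  entries <- lapply(files, readRDS)
  fp <- manifest$fingerprint
  structure(list(entries = entries, failed = list(),
                 targets = unlist(manifest$targets),
                 algorithms = unlist(manifest$algorithms),
                 seeds = unlist(manifest$seeds),
                 fingerprint = if (is.null(fp)) NULL else
                   fp_config(fp$family, fp$diameter, fp$n_bits)),
            class = "base_model_grid")
}
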