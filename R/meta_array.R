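#' @title Meta-predictor arrays
#' @description Assembly of the 200-slot prediction arrays: every
#'   compound of the meta stage is scored by all 200 base classifiers and
#'   the outputs are arranged in a fixed canonical order -- target slowest
#'   (nAChR, mAChR, AChE, BuChE, VAChT), seed in the middle (S1..S10),
#'   algorithm fastest (RF, DT, SVM, KNN) -- then reshaped row-major into
#'   the 2D/3D array layouts the detector trains on, and re-sampled into
#'   the four regimes (native, duplicate-removal, SMOTE on either).
#' @name meta_array
NULL

N_SLOTS <- 200L

#' Canonical slot order of the 200-slot array
#'
#' @return Data.frame with 200 rows: `slot` (1..200), `target`, `seed`,
#'   `algorithm`. The (target, seed, algorithm) -> slot map is bijective
#'   and version-pinned (see [slot_order_version()]).
#' @export
slot_order <- function() {
  grid <- expand.grid(algorithm = DTI_ALGORITHMS, seed = 1:10,
                      target = CHOLINERGIC_TARGETS,
                      stringsAsFactors = FALSE)
  data.frame(slot = seq_len(nrow(grid)), target = grid$target,
             seed = grid$seed, algorithm = grid$algorithm)
}

#' Flat slot index of a (target, seed, algorithm) triple
#'
#' @param target,seed,algorithm Grid coordinates (vectorized).
#' @return Integer slot index in 1..200.
#' @export
slot_index <- function(target, seed, algorithm) {
  t_i <- match(target, CHOLINERGIC_TARGETS)
  a_i <- match(algorithm, DTI_ALGORITHMS)
  if (anyNA(t_i) || anyNA(a_i) || any(seed < 1 | seed > 10))
    stop("invalid slot coordinates")
  as.integer(((t_i - 1) * 10 + (seed - 1)) * 4 + a_i)
}

# Rolling polynomial hash (mod 2^31 - 1) over the concatenated slot
# labels; pins the slot order so that persisted arrays from a different
# ordering are rejected.
label_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.slot_cache <- new.env(parent = emptyenv())

#' Slot-order version hash
#' @return Hex string identifying the canonical slot ordering.
#' @export
slot_order_version <- function() {
  if (is.null(.slot_cache$version)) {
    so <- slot_order()
    .slot_cache$version <-
      label_hash(paste(so$target, so$seed, so$algorithm,
                       collapse = "|"))
  }
  .slot_cache$version
}

SHAPE_NAMES <- c("flat", "50x4", "40x5", "5x10x4", "10x5x4")

parse_shape <- function(shape) {
  if (identical(shape, "flat")) return(NULL)
  dims <- suppressWarnings(as.integer(strsplit(shape, "x")[[1]]))
  if (anyNA(dims) || length(dims) < 2)
    stop("malformed shape: ", shape)
  if (prod(dims) != N_SLOTS)
    stop("shape ", shape, " has ", prod(dims), " cells; need ", N_SLOTS)
  dims
}

#' One compound's meta-predictor array
#'
#' Values are always stored flat in the canonical slot order; `shape`
#' is display/learning metadata, so reshaping is lossless by
#' construction.
#'
#' @param compound_id Identifier.
#' @param values Numeric vector of length 200 (canonical order).
#' @param shape `"flat"` or a string like `"50x4"` whose dimensions
#'   multiply to 200.
#' @param encoding `"binary01"`, `"binary12"` or `"probability"`.
#' @return Object of class `meta_array`.
#' @export
meta_array <- function(compound_id, values, shape = "50x4",
                       encoding = "binary01") {
  if (length(values) != N_SLOTS)
    stop("meta array needs exactly ", N_SLOTS, " values")
  parse_shape(shape)
  encoding <- match.arg(encoding, c("binary01", "binary12",
                                    "probability"))
  structure(list(compound_id = compound_id,
                 values = as.numeric(values), shape = shape,
                 encoding = encoding),
            class = "meta_array")
}

#' Reshape a meta-predictor array
#'
#' Row-major refilling of the flat canonical order; `flatten(reshape(x))`
#' is the identity.
#'
#' @param array A `meta_array`.
#' @param shape Target shape string (dimensions must multiply to 200).
#' @return The `meta_array` with the new shape.
#' @export
reshape_meta <- function(array, shape) {
  stopifnot(inherits(array, "meta_array"))
  parse_shape(shape)
  array$shape <- shape
  array
}

#' Materialize a meta-array in its declared shape
#'
#' @param x A `meta_array`.
#' @return A numeric vector (`flat`) or a row-major-filled array.
#' @export
as_array <- function(x) {
  stopifnot(inherits(x, "meta_array"))
  dims <- parse_shape(x$shape)
  if (is.null(dims)) return(x$values)
  aperm(array(x$values, dim = rev(dims)), rev(seq_along(dims)))
}

#' @export
print.meta_array <- function(x, ...) {
  cat(sprintf("<meta_array> %s [%s, %s] %d active slots\n",
              x$compound_id, x$shape, x$encoding,
              sum(x$values >= 0.5)))
  invisible(x)
}

#' Meta-array dataset
#'
#' @param values Numeric matrix, one row per compound, 200 columns in
#'   canonical slot order.
#' @param class_labels Parallel `"CWA"` / `"nonCWA"` vector.
#' @param compound_ids Identifiers (default generated).
#' @param shape,encoding As in [meta_array()].
#' @param sampling_model Provenance: `"Model01"` (native), `"Model02"`
#'   (duplicate arrays removed), `"Model03"` (SMOTE on Model01),
#'   `"Model04"` (SMOTE on Model02).
#' @param synthetic Logical vector flagging SMOTE-synthesized rows.
#' @return Object of class `array_dataset`.
#' @export
array_dataset <- function(values, class_labels, compound_ids = NULL,
                          shape = "50x4", encoding = "binary01",
                          sampling_model = "Model01",
                          synthetic = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != N_SLOTS)
    stop("array dataset needs ", N_SLOTS, " columns")
  class_labels <- as.character(class_labels)
  stopifnot(nrow(values) == length(class_labels),
            all(class_labels %in% c("CWA", "nonCWA")))
  if (is.null(compound_ids))
    compound_ids <- sprintf("C%05d", seq_len(nrow(values)))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(values))
  sampling_model <- match.arg(sampling_model,
                              c("Model01", "Model02", "Model03",
                                "Model04"))
  structure(list(values = values,
                 class_labels = class_labels,
                 compound_ids = as.character(compound_ids),
                 shape = shape,
                 encoding = match.arg(encoding,
                                      c("binary01", "binary12",
                                        "probability")),
                 sampling_model = sampling_model,
                 synthetic = as.logical(synthetic),
                 slot_order_version = slot_order_version()),
            class = "array_dataset")
}

#' @export
print.array_dataset <- function(x, ...) {
  cat(sprintf(
    "<array_dataset> %s: %d arrays [%s, %s], %d CWA / %d nonCWA (%d synthetic)\n",
    x$sampling_model, nrow(x$values), x$shape, x$encoding,
    sum(x$class_labels == "CWA"), sum(x$class_labels == "nonCWA"),
    sum(x$synthetic)))
  invisible(x)
}

subset_arrays <- function(data, idx, sampling_model = data$sampling_model) {
  array_dataset(data$values[idx, , drop = FALSE],
                data$class_labels[idx], data$compound_ids[idx],
                data$shape, data$encoding, sampling_model,
                data$synthetic[idx])
}

#' Score meta-stage compounds with the full grid
#'
#' Every compound is fingerprinted with the grid's fingerprint
#' configuration (or taken as a ready feature matrix) and scored by all
#' grid models; scores fill the canonical slot order. Binary encodings
#' threshold each model's score at 0.5.
#'
#' @param grid A complete `base_model_grid` (every target x seed x
#'   algorithm combination trained).
#' @param compounds A `meta_stage_set` (SMILES are fingerprinted) or a
#'   binary feature matrix with matching bit length.
#' @param config Optional [fp_config()]; must equal the grid's manifest
#'   configuration, otherwise a hard error is raised.
#' @param encoding `"binary01"` (default), `"binary12"` or
#'   `"probability"`.
#' @return An `array_dataset` (class labels from the meta-stage set, or
#'   all-`nonCWA` placeholders for a bare matrix).
#' @export
predict_meta <- function(grid, compounds, config = NULL,
                         encoding = "binary01") {
  stopifnot(inherits(grid, "base_model_grid"))
  if (!is.null(config)) {
    stopifnot(inherits(config, "fp_config"))
    if (!identical(unclass(config), unclass(grid$fingerprint)))
      stop("fingerprint-config mismatch: grid manifest says ",
           format(grid$fingerprint), ", got ", format(config))
  }
  if (inherits(compounds, "meta_stage_set")) {
    x <- fingerprint_matrix(compounds$smiles, grid$fingerprint)
    if (anyNA(x)) stop("unparseable SMILES in meta-stage set")
    labels <- compounds$class_labels
    ids <- compounds$compound_ids
  } else {
    x <- as.matrix(compounds)
    labels <- attr(compounds, "class_labels")
    if (is.null(labels)) labels <- rep("nonCWA", nrow(x))
    ids <- rownames(x)
  }
  needed <- slot_order()
  needed <- needed[needed$target %in% grid$targets &
                     needed$seed %in% grid$seeds &
                     needed$algorithm %in% grid$algorithms, ]
  expected <- length(grid$targets) * length(grid$seeds) *
    length(grid$algorithms)
  if (length(grid$entries) != expected)
    stop("incomplete grid: ", length(grid$entries), " of ", expected,
         " models present")
  values <- matrix(NA_real_, nrow(x), N_SLOTS)
  for (e in grid$entries) {
    s <- predict(e$model, x)
    values[, slot_index(e$spec$target, e$spec$seed,
                        e$spec$algorithm)] <- s
  }
  # grid may be a reduced lattice; unpopulated slots stay at encoding 0
  values[is.na(values)] <- 0
  values <- encode_values(values, encoding)
  array_dataset(values, labels, ids, shape = "50x4",
                encoding = encoding, sampling_model = "Model01")
}

encode_values <- function(values, encoding) {
  switch(encoding,
         probability = values,
         binary01 = (values >= 0.5) + 0,
         binary12 = (values >= 0.5) + 1,
         stop("unknown encoding: ", encoding))
}

#' Remove duplicated arrays (the Model 02 under-sampling)
#'
#' Among compounds with identical slot values and identical class label
#' only the first (input order) is kept. Identical arrays carrying
#' conflicting labels are all kept and flagged as collisions. Idempotent.
#'
#' @param data An `array_dataset`.
#' @return The deduplicated `array_dataset` (sampling model `Model02`),
#'   with attribute `collisions` listing conflicting compound ids.
#' @export
dedup_arrays <- function(data) {
  stopifnot(inherits(data, "array_dataset"))
  vec_key <- apply(data$values, 1, paste, collapse = ",")
  full_key <- paste(vec_key, data$class_labels, sep = "|")
  keep <- !duplicated(full_key)
  # collision: same values, more than one distinct label
  lab_per_vec <- tapply(data$class_labels, vec_key,
                        function(l) length(unique(l)))
  collided <- names(lab_per_vec)[lab_per_vec > 1]
  out <- subset_arrays(data, which(keep), "Model02")
  attr(out, "collisions") <-
    data$compound_ids[vec_key %in% collided]
  out
}

#' SMOTE oversampling of the minority class
#'
#' Synthesizes minority-class arrays up to the majority count: each
#' synthetic array is `x + u * (neighbour - x)` for a random minority
#' point `x`, one of its `k_neighbors` nearest minority neighbours, and
#' a single `u ~ U(0, 1)`, so every synthetic vector lies componentwise
#' on the segment between two real minority vectors. Synthetic rows are
#' flagged and left continuous (probability encoding).
#'
#' @param data An `array_dataset`.
#' @param k_neighbors Neighbourhood size (default 5).
#' @param seed Integer seed.
#' @param sampling_model Provenance label of the result (default
#'   upgrades Model01 -> Model03, Model02 -> Model04).
#' @return A balanced `array_dataset`.
#' @export
smote_oversample <- function(data, k_neighbors = 5, seed = 1,
                             sampling_model = NULL) {
  stopifnot(inherits(data, "array_dataset"))
  tab <- table(factor(data$class_labels, c("CWA", "nonCWA")))
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < k_neighbors + 1)
    stop("minority class has ", n_min, " members; SMOTE with k = ",
         k_neighbors, " needs at least ", k_neighbors + 1)
  if (is.null(sampling_model))
    sampling_model <- switch(data$sampling_model,
                             Model01 = "Model03", Model02 = "Model04",
                             data$sampling_model)
  n_new <- n_maj - n_min
  if (n_new == 0) {
    out <- subset_arrays(data, seq_len(nrow(data$values)),
                         sampling_model)
    return(out)
  }
  xm <- data$values[data$class_labels == minority, , drop = FALSE]
  nn <- FNN::get.knnx(xm, xm, k = k_neighbors + 1)$nn.index[, -1,
                                                            drop = FALSE]
  synth <- with_seed(seed, {
    base_i <- sample.int(nrow(xm), n_new, replace = TRUE)
    nbr_i <- nn[cbind(base_i, sample.int(k_neighbors, n_new,
                                         replace = TRUE))]
    u <- stats::runif(n_new)
    xm[base_i, , drop = FALSE] +
      u * (xm[nbr_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
  })
  array_dataset(rbind(data$values, synth),
                c(data$class_labels, rep(minority, n_new)),
                c(data$compound_ids, sprintf("SMOTE%05d",
                                             seq_len(n_new))),
                data$shape, "probability", sampling_model,
                c(data$synthetic, rep(TRUE, n_new)))
}

#' Build one of the four sampling regimes
#'
#' `Model01`: native imbalanced data; `Model02`: duplicated arrays
#' removed; `Model03`: SMOTE on Model01; `Model04`: SMOTE on Model02.
#'
#' @param data A native (`Model01`) `array_dataset`.
#' @param model `"Model01"`..`"Model04"`.
#' @param k_neighbors,seed Passed to [smote_oversample()].
#' @return The resampled `array_dataset`.
#' @export
sampling_regime <- function(data, model = "Model01", k_neighbors = 5,
                            seed = 1) {
  model <- match.arg(model, c("Model01", "Model02", "Model03",
                              "Model04"))
  switch(model,
         Model01 = data,
         Model02 = dedup_arrays(data),
         Model03 = smote_oversample(data, k_neighbors, seed),
         Model04 = smote_oversample(dedup_arrays(data), k_neighbors,
                                    seed))
}

#' Write an array dataset as a flat table plus manifest
#'
#' @param data An `array_dataset`.
#' @param file CSV path; a `<file>.manifest.json` sidecar records slot
#'   order, encoding, shape and sampling provenance.
#' @return `file`, invisibly.
#' @export
write_array_dataset <- function(data, file) {
  tab <- data.frame(compound_id = data$compound_ids,
                    class = data$class_labels,
                    synthetic = data$synthetic)
  vals <- as.data.frame(data$values)
  so <- slot_order()
  names(vals) <- sprintf("%s_S%02d_%s", so$target, so$seed,
                         so$algorithm)
  utils::write.csv(cbind(tab, vals), file, row.names = FALSE)
  jsonlite::write_json(
    list(shape = data$shape, encoding = data$encoding,
         sampling_model = data$sampling_model,
         slot_order_version = data$slot_order_version,
         n = nrow(data$values)),
    paste0(file, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Read an array dataset written by [write_array_dataset()]
#'
#' @param file CSV path.
#' @return An `array_dataset`.
#' @export
read_array_dataset <- function(file) {
  manifest <- jsonlite::read_json(paste0(file, ".manifest.json"))
  if (!identical(manifest$slot_order_version, slot_order_version()))
    stop("slot-order version mismatch; persisted arrays are invalid")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  array_dataset(as.matrix(tab[, -(1:3)]), tab$class, tab$compound_id,
                manifest$shape, manifest$encoding,
                manifest$sampling_model, tab$synthetic)
}
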