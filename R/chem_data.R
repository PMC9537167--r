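#' @title Activity-data cleaning and binarization
#' @description Reading of ChEMBL-export-style activity tables, target
#'   mapping, duplicate merging and active/inactive binarization for the
#'   five cholinergic targets, plus reading of the labeled SMILES lists of
#'   the meta stage (CWA vs non-CWA).
#' @name chem_data
NULL

#' The five cholinergic targets, in canonical slot order
#' @export
CHOLINERGIC_TARGETS <- c("nAChR", "mAChR", "AChE", "BuChE", "VAChT")

#' Base-model algorithms, in canonical slot order
#' @export
DTI_ALGORITHMS <- c("RF", "DT", "SVM", "KNN")

default_column_map <- function() {
  c(compound_id = "molregno", smiles = "canonical_smiles",
    standard_value = "standard_value",
    standard_relation = "standard_relation",
    standard_unit = "standard_units", tid = "tid",
    pref_name = "pref_name")
}

#' Target mapping table
#'
#' Maps ChEMBL `tid` / `pref_name` values onto the closed 5-target set.
#' The default table matches on `pref_name` patterns (BuChE additionally
#' by its known tid, 10532); an edited copy can be passed to
#' [read_activity_csv()].
#'
#' @return A data.frame with columns `target_id`, `tid` (NA = any) and
#'   `pref_pattern` (case-insensitive regular expression).
#' @export
default_target_map <- function() {
  data.frame(
    target_id = CHOLINERGIC_TARGETS,
    tid = c(NA, NA, NA, 10532L, NA),
    pref_pattern = c("nicotinic|nAChR",
                     "muscarinic|mAChR",
                     "^acetylcholinesterase$|(?<!yl)AChE$",
                     "butyrylcholinesterase|BuChE",
                     "vesicular acetylcholine transporter|VAChT"),
    stringsAsFactors = FALSE)
}

map_targets <- function(tid, pref_name, target_map) {
  out <- rep(NA_character_, length(pref_name))
  for (i in seq_len(nrow(target_map))) {
    hit <- grepl(target_map$pref_pattern[i], pref_name,
                 ignore.case = TRUE, perl = TRUE)
    if (!is.na(target_map$tid[i]))
      hit <- hit | (!is.na(tid) & tid == target_map$tid[i])
    out[hit & is.na(out)] <- target_map$target_id[i]
  }
  out
}

cleaning_report <- function(counts) {
  structure(as.list(counts), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  for (nm in names(x)) cat(sprintf("  %-18s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a ChEMBL-export-style activity CSV
#'
#' Reads a comma-separated activity table (header row; the column naming
#' of the ChEMBL activity export), maps targets to the closed five-target
#' set, and drops rows whose unit is not nM, whose standard value is
#' missing, whose target is unmappable, or (optionally) whose SMILES does
#' not parse. Every dropped row is counted in the attached cleaning
#' report.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping internal field names
#'   (`compound_id`, `smiles`, `standard_value`, `standard_relation`,
#'   `standard_unit`, `tid`, `pref_name`) to file column names.
#' @param target_map Data.frame as returned by [default_target_map()].
#' @param validate_structures Validate SMILES through the chemistry
#'   toolkit (requires the bundled Python helper); default `TRUE`.
#' @return A data.frame of activity records (columns: `compound_id`,
#'   `smiles`, `target_id`, `standard_value`, `standard_relation`) with a
#'   `cleaning_report` in `attr(, "report")`.
#' @export
read_activity_csv <- function(path, column_map = default_column_map(),
                              target_map = default_target_map(),
                              validate_structures = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  needed <- default_column_map()
  column_map <- c(column_map,
                  needed[setdiff(names(needed), names(column_map))])
  missing_cols <- setdiff(column_map, names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(
    compound_id = as.character(raw[[column_map[["compound_id"]]]]),
    smiles = as.character(raw[[column_map[["smiles"]]]]),
    standard_value = suppressWarnings(
      as.numeric(raw[[column_map[["standard_value"]]]])),
    standard_relation = as.character(
      raw[[column_map[["standard_relation"]]]]),
    standard_unit = as.character(raw[[column_map[["standard_unit"]]]]),
    stringsAsFactors = FALSE)
  df$target_id <- map_targets(
    suppressWarnings(as.integer(raw[[column_map[["tid"]]]])),
    as.character(raw[[column_map[["pref_name"]]]]), target_map)

  n_in <- nrow(df)
  drop_unit <- df$standard_unit != "nM" | is.na(df$standard_unit)
  drop_value <- is.na(df$standard_value) | df$standard_value < 0
  drop_target <- is.na(df$target_id)
  drop_smiles <- rep(FALSE, n_in)
  pending <- !(drop_unit | drop_value | drop_target)
  if (validate_structures && any(pending)) {
    ok <- validate_smiles(df$smiles[pending])
    drop_smiles[pending] <- !ok
  }
  rel <- df$standard_relation
  rel[is.na(rel) | rel == ""] <- "="
  drop_relation <- !rel %in% c("=", "<", ">", "<=", ">=")
  df$standard_relation <- rel

  keep <- !(drop_unit | drop_value | drop_target | drop_smiles |
              drop_relation)
  report <- cleaning_report(c(
    input_rows = n_in,
    unit_dropped = sum(drop_unit),
    value_dropped = sum(drop_value & !drop_unit),
    target_dropped = sum(drop_target & !drop_unit & !drop_value),
    relation_dropped = sum(drop_relation & !drop_unit & !drop_value &
                             !drop_target),
    smiles_dropped = sum(drop_smiles & keep == FALSE & !drop_unit &
                           !drop_value & !drop_target & !drop_relation),
    kept = sum(keep)))
  out <- df[keep, c("compound_id", "smiles", "target_id",
                    "standard_value", "standard_relation")]
  if (nrow(out) == 0) stop("no activity records survived cleaning of ",
                           path)
  rownames(out) <- NULL
  attr(out, "report") <- report
  class(out) <- c("activity_records", class(out))
  out
}

#' Merge duplicated activity measurements
#'
#' Collapses records to one per (compound, target): the standard value
#' becomes the median of the duplicates, and the relation is kept only
#' when all duplicates agree (otherwise `"="`). Idempotent.
#'
#' @param records Activity records as from [read_activity_csv()].
#' @return Deduplicated activity records, input order of first occurrence
#'   preserved.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  groups <- split(seq_len(nrow(records)), factor(key, levels = key[first]))
  out$standard_value <- vapply(groups, function(i)
    stats::median(records$standard_value[i]), numeric(1))
  out$standard_relation <- vapply(groups, function(i) {
    rels <- unique(records$standard_relation[i])
    if (length(rels) == 1) rels else "="
  }, character(1))
  rownames(out) <- NULL
  attr(out, "report") <- cleaning_report(c(
    input_rows = nrow(records), merged = nrow(records) - nrow(out),
    kept = nrow(out)))
  out
}

#' Labeled compound set
#'
#' @param compound_ids,smiles Parallel character vectors, no duplicate
#'   ids.
#' @param labels Parallel factor/character vector with levels
#'   `active` / `inactive`.
#' @return An object of class `labeled_compound_set`.
#' @export
labeled_compound_set <- function(compound_ids, smiles, labels) {
  stopifnot(length(compound_ids) == length(smiles),
            length(smiles) == length(labels))
  if (anyDuplicated(compound_ids))
    stop("duplicate compound_id in labeled set")
  labels <- as.character(labels)
  if (!all(labels %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'")
  structure(list(compound_ids = as.character(compound_ids),
                 smiles = as.character(smiles), labels = labels),
            class = "labeled_compound_set")
}

#' @export
print.labeled_compound_set <- function(x, ...) {
  cat(sprintf("<labeled_compound_set> %d compounds (%d active)\n",
              length(x$labels), sum(x$labels == "active")))
  invisible(x)
}

#' Binarize activity values against a potency threshold
#'
#' A compound is active when its potency is at or below `threshold_nM`
#' (lower value = stronger inhibition). Censored records are resolved
#' only when the censoring direction settles the call: `>`-censored
#' values at or above the threshold are inactive, `<`-censored values at
#' or below it are active; unresolvable censored records are dropped and
#' counted.
#'
#' @param records Activity records for a single target.
#' @param threshold_nM Positive activity cutoff in nM; default 10000
#'   (10 uM), the conventional active/inactive cutoff for interaction
#'   calls.
#' @return A [labeled_compound_set()] with a `cleaning_report` attribute.
#' @export
binarize <- function(records, threshold_nM = 10000) {
  stopifnot(threshold_nM > 0)
  if (length(unique(records$target_id)) > 1)
    stop("binarize expects records of a single target; see ",
         "per_target_sets()")
  v <- records$standard_value
  r <- records$standard_relation
  label <- rep(NA_character_, nrow(records))
  eq <- r %in% c("=")
  label[eq] <- ifelse(v[eq] <= threshold_nM, "active", "inactive")
  lo <- r %in% c("<", "<=")   # true value at or below v
  label[lo & v <= threshold_nM] <- "active"
  hi <- r %in% c(">", ">=")   # true value at or above v
  label[hi & v >= threshold_nM] <- "inactive"
  keep <- !is.na(label)
  out <- labeled_compound_set(records$compound_id[keep],
                              records$smiles[keep], label[keep])
  attr(out, "report") <- cleaning_report(c(
    input_rows = nrow(records), active = sum(label == "active",
                                             na.rm = TRUE),
    inactive = sum(label == "inactive", na.rm = TRUE),
    censored_dropped = sum(!keep)))
  out
}

#' Deduplicate and binarize per target
#'
#' @inheritParams binarize
#' @param records Activity records spanning any subset of the five
#'   targets.
#' @return Named list of [labeled_compound_set()]s, one per target
#'   present.
#' @export
per_target_sets <- function(records, threshold_nM = 10000) {
  records <- deduplicate(records)
  split_idx <- split(seq_len(nrow(records)), records$target_id)
  lapply(split_idx, function(i)
    binarize(records[i, , drop = FALSE], threshold_nM))
}

#' Read the labeled SMILES list of the meta stage
#'
#' Two-column file (whitespace- or comma-separated): SMILES and class
#' label, the class being `CWA` or `nonCWA`. Duplicate structures keep
#' their first occurrence; unknown class tokens abort.
#'
#' @param path File path.
#' @param validate_structures Canonicalize/validate SMILES via the
#'   chemistry toolkit (duplicates are then detected on canonical
#'   structures); default `TRUE`.
#' @return A `meta_stage_set`: list with `compound_ids`, `smiles`,
#'   `class_labels`, plus `prevalence` and a `cleaning_report` attribute.
#' @export
read_meta_stage <- function(path, validate_structures = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty meta-stage file: ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed meta-stage line(s): ",
                     paste(which(bad), collapse = ", "))
  smiles <- vapply(parts, `[[`, character(1), 1)
  cls <- vapply(parts, `[[`, character(1), 2)
  if (!all(cls %in% c("CWA", "nonCWA")))
    stop("unknown class token(s): ",
         paste(unique(cls[!cls %in% c("CWA", "nonCWA")]), collapse = ", "))
  n_in <- length(smiles)
  invalid <- rep(FALSE, n_in)
  key <- smiles
  if (validate_structures) {
    canon <- canonicalize_smiles(smiles)
    invalid <- is.na(canon)
    key[!invalid] <- canon[!invalid]
  }
  dup <- duplicated(key) & !invalid
  keep <- !invalid & !dup
  if (!any(keep)) stop("no valid meta-stage compounds in ", path)
  out <- meta_stage_set(compound_ids = key[keep], smiles = smiles[keep],
                        class_labels = cls[keep])
  attr(out, "report") <- cleaning_report(c(
    input_rows = n_in, smiles_dropped = sum(invalid),
    duplicates_dropped = sum(dup), kept = sum(keep)))
  out
}

#' Meta-stage compound set constructor
#'
#' @param compound_ids,smiles Parallel character vectors (ids unique).
#' @param class_labels Parallel vector of `"CWA"` / `"nonCWA"`.
#' @return An object of class `meta_stage_set` with a `prevalence`
#'   field (CWA fraction).
#' @export
meta_stage_set <- function(compound_ids, smiles, class_labels) {
  stopifnot(length(compound_ids) == length(smiles),
            length(smiles) == length(class_labels))
  if (anyDuplicated(compound_ids))
    stop("duplicate compound_id in meta-stage set")
  class_labels <- as.character(class_labels)
  if (!all(class_labels %in% c("CWA", "nonCWA")))
    stop("class labels must be 'CWA' or 'nonCWA'")
  structure(list(compound_ids = as.character(compound_ids),
                 smiles = as.character(smiles),
                 class_labels = class_labels,
                 prevalence = mean(class_labels == "CWA")),
            class = "meta_stage_set")
}

#' @export
print.meta_stage_set <- function(x, ...) {
  cat(sprintf(
    "<meta_stage_set> %d compounds: %d CWA / %d nonCWA (prevalence %.3f)\n",
    length(x$class_labels), sum(x$class_labels == "CWA"),
    sum(x$class_labels == "nonCWA"), x$prevalence))
  invisible(x)
}
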