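#' @title Circular fingerprints (ECFP / FCFP)
#' @description Generation of hashed circular fingerprints at diameters 0,
#'   2, 4 and 6 with a fixed bit length (default 1024), and assembly of the
#'   labeled learning matrix. Chemistry (SMILES parsing, canonicalization,
#'   Morgan environment enumeration) is delegated to the RDKit toolkit via
#'   a bundled batch helper; ECFP uses the standard connectivity atom
#'   invariants, FCFP the pharmacophoric feature invariants.
#' @name fingerprints
NULL

#' Fingerprint configuration
#'
#' @param family `"ECFP"` (connectivity invariants: atomic number, charge,
#'   hydrogen count, ...) or `"FCFP"` (functional-class invariants:
#'   donor/acceptor, aromaticity, ...).
#' @param diameter Even environment diameter: 0, 2, 4 or 6 (the hashing
#'   radius is `diameter / 2`).
#' @param n_bits Folded vector length; fixed per run, default 1024.
#' @return An object of class `fp_config`.
#' @export
fp_config <- function(family = "ECFP", diameter = 4, n_bits = 1024) {
  family <- match.arg(family, c("ECFP", "FCFP"))
  if (!diameter %in% c(0, 2, 4, 6))
    stop("diameter must be one of 0, 2, 4, 6")
  if (n_bits < 1) stop("n_bits must be positive")
  structure(list(family = family, diameter = as.integer(diameter),
                 n_bits = as.integer(n_bits)),
            class = "fp_config")
}

#' @export
format.fp_config <- function(x, ...)
  sprintf("%s%d/%d-bit", x$family, x$diameter, x$n_bits)

#' @export
print.fp_config <- function(x, ...) {
  cat("<fp_config>", format(x), "\n"); invisible(x)
}

#' All fingerprint configurations of a run
#'
#' The full 2-family x 4-diameter grid (8 configurations) at a fixed bit
#' length.
#'
#' @inheritParams fp_config
#' @return A list of 8 `fp_config` objects.
#' @export
fp_config_grid <- function(n_bits = 1024) {
  grid <- expand.grid(diameter = c(0, 2, 4, 6),
                      family = c("ECFP", "FCFP"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    fp_config(grid$family[i], grid$diameter[i], n_bits))
}

python_binary <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no python interpreter found on PATH")
  bin
}

fp_tool_path <- function() {
  path <- system.file("python", "fp_tool.py", package = "dtiarray")
  if (!nzchar(path)) stop("bundled fp_tool.py not found")
  path
}

run_fp_tool <- function(mode, smiles, extra = character()) {
  infile <- tempfile("smiles_", fileext = ".txt")
  on.exit(unlink(infile))
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(python_binary(),
                                  c(shQuote(fp_tool_path()), mode,
                                    shQuote(infile), extra),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("fingerprint helper failed (mode ", mode, ")")
  if (length(out) != length(smiles))
    stop("fingerprint helper returned ", length(out), " lines for ",
         length(smiles), " molecules")
  out
}

#' Canonicalize SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @return Canonical SMILES; `NA` where a string does not parse.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  out <- run_fp_tool("canon", smiles)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Validate SMILES
#'
#' @inheritParams canonicalize_smiles
#' @return Logical vector: does each string parse as a molecule?
#' @export
validate_smiles <- function(smiles) !is.na(canonicalize_smiles(smiles))

parse_bit_lines <- function(lines) {
  lapply(lines, function(l) {
    if (identical(l, "ERR")) return(NULL)
    if (!nzchar(l)) return(integer())
    as.integer(strsplit(l, " ", fixed = TRUE)[[1]])
  })
}

#' Fingerprint a batch of molecules
#'
#' @param smiles Character vector of SMILES.
#' @param config An [fp_config()].
#' @return A binary matrix, `length(smiles)` x `config$n_bits`, with
#'   `NA` rows for unparseable SMILES.
#' @export
fingerprint_matrix <- function(smiles, config = fp_config()) {
  stopifnot(inherits(config, "fp_config"))
  mat <- matrix(0L, nrow = length(smiles), ncol = config$n_bits)
  if (length(smiles) == 0) return(mat)
  bits <- parse_bit_lines(run_fp_tool(
    "fp", smiles, c(config$family, config$diameter, config$n_bits)))
  for (i in seq_along(bits)) {
    if (is.null(bits[[i]])) mat[i, ] <- NA_integer_
    else mat[i, bits[[i]] + 1L] <- 1L
  }
  mat
}

#' Fingerprint one molecule
#'
#' @inheritParams fingerprint_matrix
#' @param smiles A single SMILES string.
#' @return An integer 0/1 vector of length `config$n_bits`.
#' @export
fingerprint <- function(smiles, config = fp_config()) {
  stopifnot(length(smiles) == 1)
  v <- fingerprint_matrix(smiles, config)[1, ]
  if (anyNA(v)) stop("unparseable SMILES: ", smiles)
  v
}

#' Count distinct (unfolded) circular environments
#'
#' The number of distinct hashed environment identifiers of a molecule
#' before folding to `n_bits`; monotone non-decreasing in the diameter.
#'
#' @inheritParams fingerprint_matrix
#' @return Integer vector parallel to `smiles` (`NA` for parse failures).
#' @export
count_environments <- function(smiles, config = fp_config()) {
  out <- run_fp_tool("nenv", smiles, c(config$family, config$diameter))
  suppressWarnings(as.integer(out))
}

#' Build the labeled fingerprint learning matrix
#'
#' Fingerprints every compound of a labeled set and carries the binary
#' activity labels through, producing the matrix the classifiers train on.
#'
#' @param set A `labeled_compound_set` (see [labeled_compound_set()]).
#' @param config An [fp_config()].
#' @param on_error `"stop"` names the first failing compound and aborts;
#'   `"drop"` removes failing compounds and records them in the
#'   `dropped` attribute.
#' @return A `labeled_fp_set`: list with `compound_ids`, `x` (binary
#'   matrix) and `y` (0/1 integer labels, 1 = active).
#' @export
build_matrix <- function(set, config = fp_config(),
                         on_error = c("stop", "drop")) {
  stopifnot(inherits(set, "labeled_compound_set"))
  on_error <- match.arg(on_error)
  if (length(set$smiles) == 0) stop("empty compound set")
  mat <- fingerprint_matrix(set$smiles, config)
  bad <- which(apply(mat, 1, anyNA))
  if (length(bad) && on_error == "stop")
    stop("unparseable SMILES for compound ", set$compound_ids[bad[1]])
  keep <- setdiff(seq_len(nrow(mat)), bad)
  out <- labeled_fp_set(compound_ids = set$compound_ids[keep],
                        x = mat[keep, , drop = FALSE],
                        y = as.integer(set$labels[keep] == "active"),
                        config = config)
  attr(out, "dropped") <- set$compound_ids[bad]
  out
}

#' Labeled fingerprint set
#'
#' The learning container: a binary feature matrix plus parallel 0/1
#' activity labels.
#'
#' @param compound_ids Character vector.
#' @param x Binary matrix, one row per compound.
#' @param y Integer 0/1 labels (1 = active).
#' @param config The [fp_config()] used, or `NULL` for synthetic bits.
#' @return An object of class `labeled_fp_set`.
#' @export
labeled_fp_set <- function(compound_ids, x, y, config = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(compound_ids) == length(y))
  if (length(y) && !all(x %in% c(0L, 1L)))
    stop("feature matrix must be binary")
  if (length(unique(y)) < 2 && length(y) > 0)
    warning("degenerate label set: all compounds share one class")
  structure(list(compound_ids = as.character(compound_ids), x = x,
                 y = as.integer(y), config = config),
            class = "labeled_fp_set")
}

#' @export
print.labeled_fp_set <- function(x, ...) {
  cat(sprintf("<labeled_fp_set> %d compounds x %d bits (%d active)\n",
              nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}
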