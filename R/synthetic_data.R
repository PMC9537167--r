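#' @title Synthetic data with planted structure-activity signal
#' @description Generators emulating the statistical structure the
#'   pipeline assumes, so every stage is testable without any download:
#'   per-target fingerprint sets with a planted, disjoint informative bit
#'   block (actives enriched for the block's bits, the activity label
#'   being the majority vote of the planted bits, then flipped with a
#'   label-noise probability), a latent five-target activity profile per
#'   meta-stage compound whose CWA label follows a cholinergic
#'   conjunction rule (high CWA probability iff active on both AChE and
#'   BuChE, mirroring the nerve-agent mechanism), and a small embedded
#'   list of innocuous drug-like SMILES for end-to-end smoke tests. No
#'   real or plausible CWA structure is generated anywhere.
#' @name synthetic_data
NULL

#' Default CWA labelling rule
#'
#' Probability of the CWA class given a named 0/1 activity profile:
#' 0.9 when active on both cholinesterases (AChE and BuChE), 0.02
#' otherwise.
#'
#' @param profile Named 0/1 vector over [CHOLINERGIC_TARGETS].
#' @return CWA probability.
#' @export
default_cwa_rule <- function(profile) {
  if (profile[["AChE"]] == 1 && profile[["BuChE"]] == 1) 0.9 else 0.02
}

#' Synthetic-world specification
#'
#' @param n_per_target Compounds per target dataset (default 500).
#' @param n_bits Fingerprint length (default 1024).
#' @param informative_bits_per_target Planted bits per target (default
#'   15; disjoint across targets).
#' @param activity_noise Label flip probability in `[0, 0.5)` (default
#'   0.1).
#' @param bit_enrichment Probability that an active compound carries
#'   each planted bit (inactives: `1 - bit_enrichment`); default 0.85.
#' @param background_density Set probability of non-planted bits
#'   (default 0.05, the sparsity of real circular fingerprints).
#' @param cwa_rule Function: activity profile -> CWA probability.
#' @param n_cwa,n_noncwa Meta-stage class sizes (defaults 95 and 3126,
#'   the reference imbalance).
#' @param per_slot_accuracy For directly synthesized arrays: probability
#'   that a slot reports the compound's true activity on the slot's
#'   target (default 0.8).
#' @param seed Integer master seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_target = 500, n_bits = 1024,
                           informative_bits_per_target = 15,
                           activity_noise = 0.1,
                           bit_enrichment = 0.85,
                           background_density = 0.05,
                           cwa_rule = default_cwa_rule,
                           n_cwa = 95, n_noncwa = 3126,
                           per_slot_accuracy = 0.8, seed = 1) {
  stopifnot(activity_noise >= 0, activity_noise < 0.5,
            bit_enrichment > 0.5, bit_enrichment <= 1,
            informative_bits_per_target * length(CHOLINERGIC_TARGETS)
              <= n_bits)
  structure(list(n_per_target = n_per_target, n_bits = n_bits,
                 informative_bits_per_target =
                   informative_bits_per_target,
                 activity_noise = activity_noise,
                 bit_enrichment = bit_enrichment,
                 background_density = background_density,
                 cwa_rule = cwa_rule, n_cwa = n_cwa,
                 n_noncwa = n_noncwa,
                 per_slot_accuracy = per_slot_accuracy,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

planted_bit_sets <- function(spec) {
  m <- spec$informative_bits_per_target
  sets <- lapply(seq_along(CHOLINERGIC_TARGETS), function(i)
    seq.int((i - 1) * m + 1, i * m))
  names(sets) <- CHOLINERGIC_TARGETS
  sets
}

# Bit rows for one target block given the 0/1 activity: actives carry
# each planted bit with prob `enrich`, inactives with `1 - enrich`.
planted_block <- function(active, m, enrich) {
  n <- length(active)
  p <- ifelse(active == 1, enrich, 1 - enrich)
  matrix(stats::rbinom(n * m, 1, rep(p, m)), n, m)
}

#' Generate the per-target DTI training sets
#'
#' Each target receives a disjoint planted bit block. Per compound the
#' planted bits are drawn enriched toward a latent activity state, the
#' clean label is the majority vote of the planted bits, and the
#' observed label flips with probability `activity_noise`. All other
#' bits are background noise. Marginal class balance is ~50%.
#'
#' The clean (pre-flip) labels are attached as `attr(set, "y_clean")`
#' so that signal recovery can be measured; the flip noise caps
#' agreement with the *observed* labels at `1 - activity_noise`.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of `labeled_fp_set`, one per target, with
#'   attributes `planted_bits` and `y_clean`.
#' @export
gen_dti_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bits <- planted_bit_sets(spec)
  m <- spec$informative_bits_per_target
  with_seed(spec$seed, {
    sets <- lapply(CHOLINERGIC_TARGETS, function(t) {
      n <- spec$n_per_target
      x <- matrix(stats::rbinom(n * spec$n_bits, 1,
                                spec$background_density),
                  n, spec$n_bits)
      latent <- stats::rbinom(n, 1, 0.5)
      x[, bits[[t]]] <- planted_block(latent, m, spec$bit_enrichment)
      y_clean <- as.integer(rowSums(x[, bits[[t]], drop = FALSE]) >
                              m / 2)
      flip <- stats::rbinom(n, 1, spec$activity_noise) == 1
      y <- as.integer(xor(y_clean, flip))
      out <- suppressWarnings(labeled_fp_set(
        sprintf("%s_%04d", t, seq_len(n)), x, y))
      attr(out, "y_clean") <- y_clean
      attr(out, "planted_bits") <- bits[[t]]
      out
    })
    names(sets) <- CHOLINERGIC_TARGETS
    sets
  })
}

sample_profiles <- function(n_cwa, n_noncwa, cwa_rule) {
  k <- length(CHOLINERGIC_TARGETS)
  cwa <- list(); noncwa <- list()
  while (length(cwa) < n_cwa || length(noncwa) < n_noncwa) {
    profile <- stats::setNames(stats::rbinom(k, 1, 0.5),
                               CHOLINERGIC_TARGETS)
    is_cwa <- stats::runif(1) < cwa_rule(profile)
    if (is_cwa && length(cwa) < n_cwa)
      cwa[[length(cwa) + 1L]] <- profile
    else if (!is_cwa && length(noncwa) < n_noncwa)
      noncwa[[length(noncwa) + 1L]] <- profile
  }
  list(profiles = do.call(rbind, c(cwa, noncwa)),
       class_labels = c(rep("CWA", n_cwa), rep("nonCWA", n_noncwa)))
}

#' Generate the meta stage
#'
#' Draws a latent five-target activity profile per compound and its
#' CWA/nonCWA label from `spec$cwa_rule` (rejection sampling to the
#' exact class sizes). Two output modes:
#'
#' * `mode = "features"`: emits fingerprint-level compounds (planted
#'   bit blocks consistent with the profile, background noise
#'   elsewhere) to be scored by a trained grid -- directly, when `grid`
#'   is supplied, via [predict_meta()].
#' * `mode = "arrays"`: synthesizes the 200-slot arrays directly; each
#'   slot reports the compound's true activity on the slot's target
#'   with probability `spec$per_slot_accuracy`, independently.
#'
#' @param spec A [synthetic_spec()].
#' @param grid Optional trained `base_model_grid` (features mode).
#' @param mode `"features"` or `"arrays"`.
#' @return Features mode without grid: list with `x` (bit matrix),
#'   `class_labels`, `profiles`. With grid, or arrays mode: an
#'   `array_dataset` (with `profiles` attribute).
#' @export
gen_meta_stage <- function(spec = synthetic_spec(), grid = NULL,
                           mode = c("features", "arrays")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mode <- match.arg(mode)
  bits <- planted_bit_sets(spec)
  m <- spec$informative_bits_per_target
  with_seed(spec$seed + 1000L, {
    pops <- sample_profiles(spec$n_cwa, spec$n_noncwa, spec$cwa_rule)
    profiles <- pops$profiles
    labels <- pops$class_labels
    n <- nrow(profiles)
    ids <- sprintf("META%05d", seq_len(n))
    if (mode == "arrays") {
      so <- slot_order()
      truth <- profiles[, so$target, drop = FALSE]   # n x 200
      correct <- matrix(stats::rbinom(n * N_SLOTS, 1,
                                      spec$per_slot_accuracy),
                        n, N_SLOTS)
      values <- ifelse(correct == 1, truth, 1 - truth)
      out <- array_dataset(values, labels, ids)
      attr(out, "profiles") <- profiles
      return(out)
    }
    x <- matrix(stats::rbinom(n * spec$n_bits, 1,
                              spec$background_density),
                n, spec$n_bits)
    for (t in CHOLINERGIC_TARGETS)
      x[, bits[[t]]] <- planted_block(profiles[, t], m,
                                      spec$bit_enrichment)
    rownames(x) <- ids
    if (!is.null(grid)) {
      attr(x, "class_labels") <- labels
      out <- predict_meta(grid, x)
      attr(out, "profiles") <- profiles
      return(out)
    }
    structure(list(x = x, class_labels = labels, profiles = profiles,
                   compound_ids = ids),
              class = "synthetic_meta_stage")
  })
}

tiny_smiles <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "Clc1ccccc1",                        # chlorobenzene
  "c1ccc2c(c1)cccc2",                  # naphthalene
  "CCO", "CCCO", "CCCCO", "CC(C)O",
  "CCN(CC)CC", "CCOC(=O)C", "CC(=O)C", "CCC(=O)O",
  "c1ccccc1", "Cc1ccccc1", "COc1ccccc1", "Oc1ccccc1",
  "Nc1ccccc1", "CN(C)c1ccccc1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CCNC1",
  "O=C(O)c1ccccc1", "O=C(N)c1ccccc1", "N#Cc1ccccc1",
  "CC(N)C(=O)O", "NCC(=O)O", "CC(O)C(=O)O",
  "OCC1OC(O)C(O)C(O)C1O",              # glucose
  "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1",
  "CC(C)(C)c1ccccc1", "CCc1ccccc1O", "COC(=O)c1ccccc1",
  "CN1CCC(CC1)O", "O=S(=O)(N)c1ccccc1")

#' Embedded tiny SMILES set for smoke tests
#'
#' Forty innocuous, drug-like or simple organic structures with
#' deterministic pseudo-labels (seeded label permutation); used to
#' exercise the chemistry path end-to-end. No CWA or CWA-like structure
#' is included.
#'
#' @param seed Integer seed controlling the pseudo-label assignment.
#' @return A [labeled_compound_set()] of 40 compounds.
#' @export
gen_tiny_smiles_set <- function(seed = 1) {
  n <- length(tiny_smiles)
  labels <- with_seed(seed,
    sample(rep(c("active", "inactive"), length.out = n)))
  labeled_compound_set(sprintf("TINY%02d", seq_len(n)), tiny_smiles,
                       labels)
}

#' Write synthetic fixtures in the external input formats
#'
#' Emits the same file formats the readers consume: a ChEMBL-export
#' style activity CSV (built from the tiny SMILES set) and a two-column
#' meta-stage SMILES/class file, so the read -> clean -> binarize path
#' can be exercised from disk.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named list of the files written.
#' @export
write_synthetic_inputs <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- gen_tiny_smiles_set(seed)
  n <- length(set$smiles)
  with_seed(seed + 1L, {
    target <- sample(CHOLINERGIC_TARGETS, n, replace = TRUE)
    value <- round(stats::rlnorm(n, log(5000), 1.5), 1)
    act <- data.frame(
      molregno = seq_len(n), canonical_smiles = set$smiles,
      activity_id = 1000L + seq_len(n), assay_id = 1L,
      standard_value = value,
      standard_relation = sample(c("=", "=", "=", "<", ">"), n,
                                 replace = TRUE),
      standard_units = "nM",
      tid = ifelse(target == "BuChE", 10532L, 0L),
      target_type = "SINGLE PROTEIN", pref_name = target,
      organism = "Homo sapiens")
    cls <- sample(c("CWA", "nonCWA"), n, replace = TRUE,
                  prob = c(0.15, 0.85))
    meta <- data.frame(smiles = set$smiles, class = cls)
  })
  act_file <- file.path(dir, "synthetic_activities.csv")
  meta_file <- file.path(dir, "synthetic_meta_stage.csv")
  utils::write.csv(act, act_file, row.names = FALSE, quote = FALSE)
  utils::write.table(meta, meta_file, row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = ",")
  list(activities = act_file, meta_stage = meta_file)
}
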