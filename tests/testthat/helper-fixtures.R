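# Shared fixtures, built in code. The small trained grid is expensive
# enough to build once and reuse across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Tiny but learnable synthetic world: 5 targets, 64 bits, 80 compounds.
tiny_spec <- function(seed = 7)
  synthetic_spec(n_per_target = 80, n_bits = 64,
                 informative_bits_per_target = 9, activity_noise = 0.1,
                 n_cwa = 25, n_noncwa = 100, seed = seed)

tiny_sets <- function() {
  if (is.null(.fixture_cache$sets))
    .fixture_cache$sets <- gen_dti_dataset(tiny_spec())
  .fixture_cache$sets
}

# Complete 5-target x 4-algorithm x 2-seed grid (40 models).
tiny_grid <- function() {
  if (is.null(.fixture_cache$grid))
    .fixture_cache$grid <- train_grid(tiny_sets(),
                                      grid_specs(seeds = 1:2))
  .fixture_cache$grid
}

tiny_arrays <- function() {
  if (is.null(.fixture_cache$arrays))
    .fixture_cache$arrays <- gen_meta_stage(tiny_spec(),
                                            grid = tiny_grid())
  .fixture_cache$arrays
}

# Direct-array meta stage (no grid needed) at a given slot fidelity.
direct_arrays <- function(per_slot_accuracy = 0.9, n_cwa = 40,
                          n_noncwa = 200, seed = 5)
  gen_meta_stage(synthetic_spec(per_slot_accuracy = per_slot_accuracy,
                                n_cwa = n_cwa, n_noncwa = n_noncwa,
                                seed = seed),
                 mode = "arrays")

# Independent brute-force oracles ------------------------------------

# ROC-AUC by exhaustive positive-negative pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Average precision by direct rank walk (one step per ranked item).
oracle_ap <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  ap <- 0; tp <- 0
  n_pos <- sum(labels)
  k <- 1
  while (k <= length(y)) {
    # advance over a whole tie block at once
    j <- k
    while (j < length(y) && s[j + 1] == s[k]) j <- j + 1
    tp_new <- tp + sum(y[k:j])
    prec <- tp_new / j
    ap <- ap + (tp_new - tp) / n_pos * prec
    tp <- tp_new
    k <- j + 1
  }
  ap
}

random_confusion_instance <- function(n) {
  pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
  lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
  list(pred = pred, lab = lab)
}
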