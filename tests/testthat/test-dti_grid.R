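balanced_set <- function(n = 100, p = 32, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rbinom(n * p, 1, 0.3 + 0.4 * rep(y, p)), n, p)
  labeled_fp_set(sprintf("c%03d", 1:n), x, y)
}

test_that("stratified 70:30 split has exact per-class arithmetic", {
  halves <- split_set(balanced_set(100), split_spec(seed = 5))
  expect_equal(length(halves$train$y), 70)
  expect_equal(length(halves$test$y), 30)
  expect_equal(sum(halves$train$y), 35)
  expect_equal(sum(halves$test$y), 15)
  expect_setequal(c(halves$train_idx, halves$test_idx), 1:100)
  expect_length(intersect(halves$train_idx, halves$test_idx), 0)
})

test_that("identical split seeds give identical partitions; seeds differ otherwise", {
  s <- balanced_set(80)
  a <- split_set(s, split_spec(seed = 3))
  b <- split_set(s, split_spec(seed = 3))
  c <- split_set(s, split_spec(seed = 4))
  expect_identical(a$train_idx, b$train_idx)
  expect_false(identical(a$train_idx, c$train_idx))
})

test_that("a class with fewer than 2 members fails stratification", {
  y <- c(rep(0L, 9), 1L)
  s <- labeled_fp_set(letters[1:10], matrix(0:1, 10, 4), y)
  expect_error(split_set(s, split_spec()), "stratification")
})

test_that("cross-validation validates every sample exactly once", {
  s <- balanced_set(100, seed = 2)
  cv <- cross_validate(s, "DT", k = 10, seed = 1)
  expect_equal(sort(unique(cv$assignment)), 1:10)
  expect_equal(as.vector(table(cv$assignment)), rep(10, 10))
  expect_equal(length(cv$folds), 10)
  expect_true(all(c("mean", "sd") %in% names(cv$summary)))
  expect_error(cross_validate(s, "DT", k = 200), "exceeds")
  expect_error(cross_validate(s, "DT", k = 60), "minority")
})

test_that("cross-validation on separable data reaches near-perfect accuracy", {
  set.seed(8)
  n <- 100
  y <- rep(0:1, each = 50)
  x <- matrix(rbinom(n * 16, 1, 0.05), n, 16)
  x[, 1] <- y                       # perfectly informative bit
  s <- labeled_fp_set(sprintf("c%d", 1:n), x, y)
  cv <- cross_validate(s, "DT", k = 5, seed = 1)
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gt(acc, 0.95)
})

test_that("the grid has |targets| x |algorithms| x |seeds| members", {
  expect_length(grid_specs(), 200)   # 5 x 4 x 10
  expect_length(grid_specs(targets = "AChE", algorithms = "RF",
                           seeds = 1:3), 3)
  grid <- tiny_grid()
  expect_length(grid$entries, 5 * 4 * 2)
})

test_that("test metrics come from the held-out portion and behave sanely", {
  grid <- tiny_grid()
  for (e in grid$entries[1:4]) {
    expect_equal(length(e$test_scores),
                 round(nrow(tiny_sets()[[e$spec$target]]$x) * 0.3))
    expect_lte(e$test_report$accuracy, 1)
  }
  # deterministic learners reproduce bit-identically on retrain
  e <- Filter(function(e) e$spec$algorithm == "DT",
              grid$entries)[[1]]
  again <- train_grid(tiny_sets(),
                      list(e$spec))$entries[[1]]
  expect_identical(again$test_scores, e$test_scores)
})

test_that("ensemble-AUC is the seed mean and stays inside the seed range", {
  grid <- tiny_grid()
  models <- Filter(function(e)
    e$spec$target == "AChE" && e$spec$algorithm == "RF", grid$entries)
  per_seed <- vapply(models, function(e)
    roc_auc(e$test_scores, e$test_labels), numeric(1))
  expect_equal(ensemble_auc(models), mean(per_seed))
  expect_gte(ensemble_auc(models), min(per_seed))
  expect_lte(ensemble_auc(models), max(per_seed))
  # identical models: ensemble reduces to the individual AUC
  expect_warning(one <- ensemble_auc(models[1]), "fewer than 2")
  expect_equal(one, per_seed[1])
  expect_error(ensemble_auc(grid$entries[1:3]), "share")
})

test_that("averaged-probability ensemble definition is selectable", {
  grid <- tiny_grid()
  models <- Filter(function(e)
    e$spec$target == "AChE" && e$spec$algorithm == "RF", grid$entries)
  s <- tiny_sets()$AChE
  auc <- ensemble_auc(models, method = "averaged_prob",
                      newdata = s$x, labels = s$y)
  expect_true(auc >= 0 && auc <= 1)
  expect_error(ensemble_auc(models, method = "averaged_prob"),
               "common evaluation set")
})

test_that("select_best matches a brute-force scan of the grid", {
  grid <- tiny_grid()
  sel <- select_best(grid)
  expect_equal(nrow(sel), 5)
  ens <- ensemble_auc_table(grid)
  for (i in seq_len(nrow(sel))) {
    t <- sel$target[i]
    best_ens <- max(ens$ensemble_auc[ens$target == t])
    expect_equal(sel$ensemble_auc[i], best_ens, tolerance = 1e-12)
    # chosen seed maximizes per-seed test AUC within (target, algorithm)
    models <- Filter(function(e)
      e$spec$target == t && e$spec$algorithm == sel$algorithm[i],
      grid$entries)
    per_seed <- vapply(models, function(e)
      roc_auc(e$test_scores, e$test_labels), numeric(1))
    expect_equal(sel$test_auc[i], max(per_seed), tolerance = 1e-12)
  }
})

test_that("grid persistence round-trips through the manifest", {
  grid <- tiny_grid()
  dir <- tempfile("griddir")
  save_grid(grid, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_grid(dir)
  expect_equal(length(back$entries), length(grid$entries))
  e0 <- grid$entries[[1]]; s <- tiny_sets()[[e0$spec$target]]
  eb <- Filter(function(e)
    identical(e$spec[c("target", "algorithm", "seed")],
              e0$spec[c("target", "algorithm", "seed")]),
    back$entries)[[1]]
  expect_identical(predict(eb$model, s$x), predict(e0$model, s$x))
})
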