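test_that("slot order is a bijection over the 200 grid cells", {
  so <- slot_order()
  expect_equal(nrow(so), 200)
  idx <- slot_index(so$target, so$seed, so$algorithm)
  expect_equal(idx, 1:200)            # canonical order, no collision
  # axis ordering: target slowest, seed middle, algorithm fastest
  expect_equal(so$target[1:4], rep("nAChR", 4))
  expect_equal(so$algorithm[1:4], DTI_ALGORITHMS)
  expect_equal(so$seed[c(1, 5)], c(1, 2))
  expect_error(slot_index("AChE", 11, "RF"), "invalid")
  expect_match(slot_order_version(), "^[0-9a-f]+$")
})

# row-major flattening oracle, independent of the package internals
flatten_rowmajor <- function(arr) {
  if (is.null(dim(arr))) return(as.vector(arr))
  as.vector(aperm(arr, rev(seq_along(dim(arr)))))
}

test_that("reshape is lossless across all four shapes (roundtrip identity)", {
  set.seed(21)
  for (i in 1:50) {
    v <- if (i %% 2) runif(200) else rbinom(200, 1, 0.3)
    a <- meta_array(paste0("r", i), v, "flat", "probability")
    for (shape in c("50x4", "40x5", "5x10x4", "10x5x4")) {
      b <- reshape_meta(a, shape)
      expect_identical(b$values, as.numeric(v))        # stored flat
      expect_equal(flatten_rowmajor(as_array(b)),      # materialized
                   as.numeric(v))
    }
  }
})

test_that("row-major index arithmetic matches hand-computed positions", {
  v <- seq_len(200)
  a <- meta_array("c", v, "50x4")
  m50 <- as_array(a)                       # 50 x 4, row-major fill
  expect_equal(m50[1, ], 1:4)
  expect_equal(m50[2, 1], 5)
  m40 <- as_array(reshape_meta(a, "40x5")) # 40 x 5, row-major refill
  # element (0,4) zero-based of the new layout = flat slot 5
  # = element (1,0) zero-based of the old [50x4] layout
  expect_equal(m40[1, 5], m50[2, 1])
  t3 <- as_array(reshape_meta(a, "5x10x4"))
  expect_equal(t3[1, 1, ], 1:4)
  expect_equal(t3[2, 1, 1], 41)            # second target block
  expect_equal(dim(t3), c(5, 10, 4))
})

test_that("invalid shapes are rejected", {
  v <- rep(0, 200)
  expect_error(meta_array("c", v, "7x7"), "49")
  expect_error(reshape_meta(meta_array("c", v), "10x10"), "100")
  expect_error(meta_array("c", rep(0, 100)), "200")
})

test_that("predict_meta produces one 200-slot array per compound", {
  arrays <- tiny_arrays()
  expect_equal(ncol(arrays$values), 200)
  expect_equal(nrow(arrays$values), 125)  # 25 CWA + 100 nonCWA
  expect_true(all(arrays$values %in% c(0, 1)))
  expect_equal(arrays$sampling_model, "Model01")
})

test_that("planted single-target activity concentrates in that target's block", {
  # compounds active on AChE only: the AChE slot block should fire
  # far more often than the other blocks
  spec <- tiny_spec()
  grid <- tiny_grid()
  set.seed(33)
  n <- 30
  x <- matrix(rbinom(n * spec$n_bits, 1, spec$background_density),
              n, spec$n_bits)
  m <- spec$informative_bits_per_target
  ache_block <- which(CHOLINERGIC_TARGETS == "AChE")
  cols <- ((ache_block - 1) * m + 1):(ache_block * m)
  x[, cols] <- rbinom(n * m, 1, spec$bit_enrichment)
  arr <- predict_meta(grid, x)
  so <- slot_order()
  populated <- so$seed %in% grid$seeds   # reduced grid: other slots are 0
  ache_rate <- mean(arr$values[, so$target == "AChE" & populated])
  other_rate <- mean(arr$values[, so$target != "AChE" & populated])
  expect_gt(ache_rate, 0.5)
  expect_lt(other_rate, 0.5)
  expect_gt(ache_rate, other_rate + 0.3)
})

test_that("fingerprint-config mismatch against the grid manifest is fatal", {
  grid <- tiny_grid()
  expect_error(predict_meta(grid, matrix(0, 2, 64),
                            config = fp_config("FCFP", 2)),
               "mismatch")
})

test_that("encodings: binary01 thresholds at 0.5, binary12 shifts by one", {
  spec <- tiny_spec()
  a12 <- predict_meta(tiny_grid(), gen_meta_stage(spec)$x,
                      encoding = "binary12")
  expect_true(all(a12$values %in% c(1, 2)))
  prob <- predict_meta(tiny_grid(), gen_meta_stage(spec)$x,
                       encoding = "probability")
  expect_true(all(prob$values >= 0 & prob$values <= 1))
  expect_equal((prob$values >= 0.5) + 1, a12$values)
})

test_that("dedup_arrays keeps first duplicates, flags label collisions, idempotent", {
  v <- matrix(rbinom(5 * 200, 1, 0.5), 5, 200)
  vals <- rbind(v[1, ], v[1, ], v[2, ], v[3, ], v[3, ])
  labels <- c("nonCWA", "nonCWA", "CWA", "CWA", "nonCWA")
  d <- array_dataset(vals, labels,
                     compound_ids = sprintf("c%d", 1:5))
  out <- dedup_arrays(d)
  # rows 1&2 merge; rows 4&5 collide (same values, both labels kept)
  expect_equal(nrow(out$values), 4)
  expect_setequal(attr(out, "collisions"), c("c4", "c5"))
  expect_equal(out$sampling_model, "Model02")
  again <- dedup_arrays(out)
  expect_equal(again$values, out$values)
  expect_equal(again$class_labels, out$class_labels)
  # all-distinct dataset passes through unchanged
  distinct <- array_dataset(v, rep(c("CWA", "nonCWA"), c(2, 3)))
  expect_equal(nrow(dedup_arrays(distinct)$values), 5)
})

test_that("SMOTE balances classes by convex minority combinations", {
  set.seed(55)
  vals <- rbind(matrix(runif(10 * 200), 10, 200),
                matrix(runif(90 * 200), 90, 200))
  d <- array_dataset(vals, rep(c("CWA", "nonCWA"), c(10, 90)),
                     encoding = "probability")
  out <- smote_oversample(d, k_neighbors = 5, seed = 2)
  expect_equal(as.vector(table(out$class_labels)[c("CWA", "nonCWA")]),
               c(90, 90))
  expect_equal(sum(out$synthetic), 80)
  # componentwise convexity within the minority envelope
  minority <- vals[1:10, ]
  lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
  synth <- out$values[out$synthetic, ]
  expect_true(all(sweep(synth, 2, lo, ">=") | abs(sweep(synth, 2, lo,
                                                        "-")) < 1e-12))
  expect_true(all(synth <= matrix(hi, nrow(synth), 200,
                                  byrow = TRUE) + 1e-12))
  # reproducibility and the error contract
  out2 <- smote_oversample(d, k_neighbors = 5, seed = 2)
  expect_identical(out$values, out2$values)
  small <- array_dataset(vals[c(1:3, 11:90), ],
                         rep(c("CWA", "nonCWA"), c(3, 80)))
  expect_error(smote_oversample(small, k_neighbors = 5), "at least 6")
})

test_that("identical minority points yield identical synthetics", {
  one <- matrix(rbinom(200, 1, 0.5), 1, 200)
  vals <- rbind(one[rep(1, 6), ], matrix(rbinom(20 * 200, 1, 0.5),
                                         20, 200))
  d <- array_dataset(vals, rep(c("CWA", "nonCWA"), c(6, 20)))
  out <- smote_oversample(d, k_neighbors = 5, seed = 3)
  synth <- out$values[out$synthetic, , drop = FALSE]
  expect_true(all(apply(synth, 1, function(r)
    all(abs(r - one[1, ]) < 1e-12))))
})

test_that("sampling regimes obey the count contracts", {
  arrays <- tiny_arrays()
  m01 <- sampling_regime(arrays, "Model01")
  m02 <- sampling_regime(arrays, "Model02")
  m03 <- sampling_regime(arrays, "Model03", seed = 1)
  m04 <- sampling_regime(arrays, "Model04", seed = 1)
  expect_true(all(m02$compound_ids %in% m01$compound_ids))
  maj01 <- max(table(m01$class_labels))
  maj02 <- max(table(m02$class_labels))
  expect_equal(nrow(m03$values), 2 * maj01)
  expect_equal(nrow(m04$values), 2 * maj02)
})

test_that("array datasets persist as flat table + manifest and reload", {
  arrays <- direct_arrays(n_cwa = 8, n_noncwa = 20)
  f <- file.path(tempfile("arr"), "arrays.csv")
  dir.create(dirname(f))
  write_array_dataset(arrays, f)
  expect_true(file.exists(paste0(f, ".manifest.json")))
  back <- read_array_dataset(f)
  expect_equal(back$values, arrays$values, ignore_attr = TRUE)
  expect_equal(back$class_labels, arrays$class_labels)
  expect_equal(back$sampling_model, arrays$sampling_model)
})
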