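# File-format fixtures are written to tempfiles in code; SMILES
# validation runs through the real chemistry helper only where the test
# is about structures.

write_activity_fixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- paste("molregno", "canonical_smiles", "activity_id",
                  "assay_id", "standard_value", "standard_relation",
                  "standard_units", "tid", "target_type", "pref_name",
                  "organism", sep = ",")
  writeLines(c(header, rows), path)
  path
}

arow <- function(id, smiles, value, relation = "=", unit = "nM",
                 tid = 0, pref = "Acetylcholinesterase")
  sprintf('%d,%s,%d,1,%s,%s,%s,%d,SINGLE PROTEIN,%s,Homo sapiens',
          id, smiles, 100 + id, as.character(value), relation, unit,
          tid, pref)

test_that("read_activity_csv applies the unit filter and reports drops", {
  path <- write_activity_fixture(c(
    arow(1, "CCO", 100), arow(2, "CCN", 200, unit = "ug.mL-1"),
    arow(3, "CCC", 300)))
  rec <- read_activity_csv(path, validate_structures = FALSE)
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "report")$unit_dropped, 1)
  expect_equal(rec$compound_id, c("1", "3"))  # order preserved
})

test_that("malformed SMILES rows are dropped and counted", {
  path <- write_activity_fixture(c(
    arow(1, "CCO", 100), arow(2, "C1CC", 200), arow(3, "CCC", 300)))
  rec <- read_activity_csv(path)   # structure validation on
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "report")$smiles_dropped, 1)
})

test_that("a well-formed fixture passes through intact, in order", {
  path <- write_activity_fixture(vapply(1:5, function(i)
    arow(i, "CCO", i * 100), character(1)))
  rec <- read_activity_csv(path, validate_structures = FALSE)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$standard_value, (1:5) * 100)
})

test_that("missing mandatory columns and empty results raise errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_activity_csv(path, validate_structures = FALSE),
               "mandatory column")
  only_bad <- write_activity_fixture(arow(1, "CCO", 5, unit = "uM"))
  expect_error(read_activity_csv(only_bad, validate_structures = FALSE),
               "survived cleaning")
})

test_that("target mapping covers the five targets and BuChE's tid", {
  path <- write_activity_fixture(c(
    arow(1, "CCO", 1, pref = "Nicotinic acetylcholine receptor"),
    arow(2, "CCO", 2, pref = "Muscarinic acetylcholine receptor M1"),
    arow(3, "CCO", 3, pref = "Acetylcholinesterase"),
    arow(4, "CCO", 4, tid = 10532, pref = "Cholinesterase"),
    arow(5, "CCO", 5, pref = "Vesicular acetylcholine transporter"),
    arow(6, "CCO", 6, pref = "Dopamine receptor")))
  rec <- read_activity_csv(path, validate_structures = FALSE)
  expect_setequal(rec$target_id, CHOLINERGIC_TARGETS)
  expect_equal(attr(rec, "report")$target_dropped, 1)
})

records_df <- function(ids, targets, values, relations = "=") {
  structure(data.frame(compound_id = as.character(ids),
                       smiles = "CCO", target_id = targets,
                       standard_value = values,
                       standard_relation = rep_len(relations,
                                                   length(values)),
                       stringsAsFactors = FALSE),
            class = c("activity_records", "data.frame"))
}

test_that("deduplicate merges by median and reconciles relations", {
  rec <- records_df(c(1, 1), "AChE", c(100, 300))
  out <- deduplicate(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$standard_value, 200)  # median of {100, 300}
  single <- deduplicate(records_df(1, "AChE", 50))
  expect_equal(single$standard_value, 50)
  mixed <- deduplicate(records_df(c(1, 1), "AChE", c(10, 20),
                                  relations = c("<", "=")))
  expect_equal(mixed$standard_relation, "=")
  agree <- deduplicate(records_df(c(1, 1), "AChE", c(10, 20),
                                  relations = c("<", "<")))
  expect_equal(agree$standard_relation, "<")
})

test_that("deduplicate is idempotent", {
  set.seed(10)
  rec <- records_df(sample(1:6, 20, replace = TRUE),
                    sample(c("AChE", "BuChE"), 20, replace = TRUE),
                    runif(20, 1, 1e5),
                    sample(c("=", "<", ">"), 20, replace = TRUE))
  once <- deduplicate(rec)
  twice <- deduplicate(once)
  attr(once, "report") <- attr(twice, "report") <- NULL
  expect_equal(twice, once)
})

test_that("binarize resolves values and censored relations against the cutoff", {
  rec <- records_df(1:3, "AChE", c(5000, 50000, 5000),
                    relations = c("=", ">", ">"))
  out <- binarize(rec, threshold_nM = 10000)
  expect_equal(out$labels, c("active", "inactive"))
  expect_equal(attr(out, "report")$censored_dropped, 1)
  lt <- binarize(records_df(1, "AChE", 500, "<"), 10000)
  expect_equal(lt$labels, "active")
})

test_that("binarize partitions resolvable records exactly", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    rec <- records_df(seq_len(n), "AChE", rlnorm(n, log(1e4), 2),
                      sample(c("=", "<", ">", "<=", ">="), n,
                             replace = TRUE))
    out <- binarize(rec, 10000)
    rep <- attr(out, "report")
    expect_equal(rep$active + rep$inactive + rep$censored_dropped, n)
    expect_equal(length(out$labels), rep$active + rep$inactive)
  }
})

test_that("per_target_sets chains dedup and binarize per target", {
  rec <- records_df(c(1, 1, 2, 3), c("AChE", "AChE", "AChE", "BuChE"),
                    c(100, 300, 20000, 50))
  sets <- per_target_sets(rec)
  expect_named(sets, c("AChE", "BuChE"))
  expect_equal(sets$AChE$labels, c("active", "inactive"))
})

test_that("read_meta_stage validates classes, deduplicates, reports prevalence", {
  path <- tempfile()
  writeLines(c(sprintf("C%sO CWA", strrep("C", 1:3)),
               sprintf("c1ccccc1C%s nonCWA", strrep("N", 1:30))), path)
  ms <- read_meta_stage(path, validate_structures = FALSE)
  expect_equal(ms$prevalence, 3 / 33, tolerance = 1e-12)

  dup <- tempfile(); writeLines(c("CCO CWA", "CCO CWA", "CCN nonCWA"),
                                dup)
  msd <- read_meta_stage(dup, validate_structures = FALSE)
  expect_equal(attr(msd, "report")$duplicates_dropped, 1)

  bad <- tempfile(); writeLines("CCO weapon", bad)
  expect_error(read_meta_stage(bad, validate_structures = FALSE),
               "unknown class")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_meta_stage(empty, validate_structures = FALSE),
               "empty")
})

test_that("canonical duplicate detection catches same molecule, different SMILES", {
  path <- tempfile()
  writeLines(c("CCO CWA", "OCC CWA", "CCN nonCWA"), path)
  ms <- read_meta_stage(path, validate_structures = TRUE)
  expect_equal(attr(ms, "report")$duplicates_dropped, 1)
  expect_equal(length(ms$smiles), 2)
})

test_that("cleaning report counts reconcile with input rows everywhere", {
  files <- write_synthetic_inputs(tempfile("simdir"), seed = 3)
  rec <- read_activity_csv(files$activities)
  rep <- attr(rec, "report")
  expect_equal(rep$kept + rep$unit_dropped + rep$value_dropped +
                 rep$target_dropped + rep$relation_dropped +
                 rep$smiles_dropped, rep$input_rows)
  ms <- read_meta_stage(files$meta_stage)
  mrep <- attr(ms, "report")
  expect_equal(mrep$kept + mrep$smiles_dropped +
                 mrep$duplicates_dropped, mrep$input_rows)
})
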