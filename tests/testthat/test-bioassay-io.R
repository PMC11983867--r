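# Reading outcome tables and resolving them to per-(assay, compound) labels.

test_that("read_assay_results parses, normalizes and rejects outcomes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\tcompound_id\toutcome\tac50_uM\tsource",
               "A1\tC1\tactive\t\thts",
               "A1\tC2\tInactive\t\thts",
               "A2\tC1\tunspecified\t12.5\tliterature"), f)
  rec <- read_assay_results(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(as.character(rec$outcome),
               c("active", "inactive", "unspecified"))
  expect_equal(rec$ac50_uM, c(NA, NA, 12.5))
  expect_equal(as.character(rec$source), c("hts", "hts", "literature"))

  writeLines(c("assay_id\tcompound_id\toutcome",
               "A1\tC1\thit"), f)
  expect_error(read_assay_results(f), "hit.*allowed|allowed.*hit")

  writeLines(c("aid\tcid\tresult",
               "A1\tC1\tactive"), f)
  expect_error(read_assay_results(f), "assay_id")
  rec2 <- read_assay_results(f, columns = list(assay_id = "aid",
                                               compound_id = "cid",
                                               outcome = "result"))
  expect_equal(rec2$assay_id, "A1")

  writeLines(c("assay_id\tcompound_id\toutcome\tac50_uM",
               "A1\tC1\tunspecified\ttwelve"), f)
  expect_error(read_assay_results(f), "AC50.*line")
})

test_that("csv dialect and gzip transparency work", {
  f <- withr::local_tempfile(fileext = ".csv.gz")
  con <- gzfile(f, "w")
  writeLines(c("assay_id,compound_id,outcome",
               "A1,C1,inconclusive"), con)
  close(con)
  rec <- read_assay_results(f)
  expect_equal(as.character(rec$outcome), "inconclusive")
})

test_that("AC50 rule classifies ambiguous literature records", {
  rec <- records_df("A1", c("C1", "C2", "C3"), "unspecified",
                    ac50 = c(1000, 1200, NA), source = "literature")
  out <- classify_literature_outcome(rec)
  expect_equal(as.character(out$outcome), c("active", "inactive", "inactive"))

  # monotone: lowering AC50 never flips active -> inactive
  ac <- sort(stats::runif(50, 0, 3000), decreasing = TRUE)
  lab <- as.character(classify_literature_outcome(
    records_df("A1", sprintf("C%02d", 1:50), "inconclusive",
               ac50 = ac, source = "literature"))$outcome)
  first_active <- match("active", lab)
  if (!is.na(first_active)) {
    expect_true(all(lab[first_active:50] == "active"))
  }

  expect_error(classify_literature_outcome(
    records_df("A1", "C1", "unspecified", source = "hts")), "literature")
  expect_error(classify_literature_outcome(
    records_df("A1", "C1", "active", source = "literature")), "already")
})

test_that("hts records without a curation path are dropped with a message", {
  rec <- records_df(c("A1", "A2"), "C1", c("inactive", "inconclusive"))
  expect_message(out <- resolve_ambiguous_outcomes(rec), "dropping 1")
  expect_equal(nrow(out), 1L)
  expect_equal(as.character(out$outcome), "inactive")
})

test_that("harmonize_outcomes applies the conflict rule per assay", {
  rec <- records_df(c("A1", "A1", "A1", "A2"), c("C1", "C1", "C1", "C1"),
                    c("active", "inactive", "inactive", "inactive"))
  out <- harmonize_outcomes(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(as.character(out$label[out$assay_id == "A1"]), "active")
  expect_equal(as.character(out$label[out$assay_id == "A2"]), "inactive")

  unan <- harmonize_outcomes(records_df(c("A1", "A1"), "C1", "inactive"))
  expect_equal(as.character(unan$label), "inactive")

  expect_error(harmonize_outcomes(records_df("A1", "C1", "unspecified")),
               "resolve_ambiguous_outcomes")
})

test_that("harmonization is idempotent and order-independent", {
  set.seed(1)
  rec <- records_df(sample(c("A1", "A2", "A3"), 40, TRUE),
                    sample(c("C1", "C2"), 40, TRUE),
                    sample(c("active", "inactive"), 40, TRUE,
                           prob = c(.3, .7)))
  base <- harmonize_outcomes(rec)
  for (k in 1:5) {
    perm <- rec[sample.int(nrow(rec)), ]
    expect_equal(harmonize_outcomes(perm), base)
  }
  # feeding the result back (as records) reproduces itself
  again <- harmonize_outcomes(records_df(base$assay_id, base$compound_id,
                                         as.character(base$label)))
  expect_equal(again, base)
})

test_that("compound profiles count categories per axis", {
  out <- harmonize_outcomes(records_df(c("A1", "A2", "A3"), "C1", "inactive"))
  cats <- categories_df(c("A1", "A2", "A3"), c("k1", "k1", "k2"),
                        type = c("t1", "t2", "t2"),
                        target = c("T1", NA, "T2"))
  prof <- build_compound_profiles(out, cats)
  p <- prof[["C1"]]
  expect_equal(p$n_assay, 3L)
  expect_false(p$any_active)
  expect_equal(p$counts$cluster, c(k1 = 2L, k2 = 1L))
  expect_equal(p$counts$type, c(t1 = 1L, t2 = 2L))
  expect_equal(p$counts$target, c(T1 = 1L, T2 = 1L))
  # axis sums equal N_assay restricted to annotated assays
  expect_equal(sum(p$counts$cluster), p$n_assay)
  expect_equal(sum(p$counts$target), 2L)

  act <- build_compound_profiles(
    harmonize_outcomes(records_df(paste0("A", 1:10), "C2",
                                  c("active", rep("inactive", 9)))),
    categories_df(paste0("A", 1:10), "k1"))
  expect_true(act[["C2"]]$any_active)

  empty <- build_compound_profiles(
    harmonize_outcomes(records_df(character(), character(), character())),
    cats)
  expect_length(empty, 0L)

  expect_error(build_compound_profiles(out, categories_df("A1", "k1")),
               "A2")
})

test_that("resolved outcome tables round-trip through TSV", {
  out <- harmonize_outcomes(records_df(c("A1", "A2"), "C1",
                                       c("active", "inactive")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_resolved_outcomes(out, f)
  expect_equal(read_resolved_outcomes(f), out)
})
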