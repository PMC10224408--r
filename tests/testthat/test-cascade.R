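test_that("a Cramer-III flagged compound with modest drug-likeness falls at step 3", {
  lib <- clean_library("t1")
  ann <- benign_annotation("t1")
  ann$cramer_class <- "III"
  ann$mutagenicity <- TRUE
  ann$overall_druglikeness <- 0.85
  res <- run_cascade(lib, ann)
  expect_equal(res$records$outcome, "eliminated")
  expect_equal(res$records$step, 3L)
  clauses <- res$records$triggered[[1]]
  expect_setequal(clauses$field,
                  c("cramer_class", "n_tox_flags", "overall_druglikeness"))
})

test_that("step 3 treats 'does not exceed 0.90' inclusively", {
  lib <- clean_library("t1")
  ann <- benign_annotation("t1")
  ann$cramer_class <- "III"
  ann$mutagenicity <- TRUE
  ann$overall_druglikeness <- 0.90
  expect_equal(run_cascade(lib, ann)$records$step, 3L)
  ann$overall_druglikeness <- 0.901
  expect_equal(run_cascade(lib, ann)$records$outcome, "retained")
})

test_that("a clean compound with benign annotations is retained", {
  res <- run_cascade(clean_library("ok"), benign_annotation("ok"))
  expect_equal(res$records$outcome, "retained")
  expect_true(is.na(res$records$step))
})

test_that("two toxicity flags trigger step 1 before anything else", {
  ann <- benign_annotation("t")
  ann$mutagenicity <- TRUE
  ann$tumorigenesis <- TRUE
  ann$cramer_class <- "III"
  ann$overall_druglikeness <- 0.5
  res <- run_cascade(clean_library("t"), ann)
  expect_equal(res$records$step, 1L)
})

test_that("step 2 annotation routes fire independently of the rule route", {
  for (tweak in list(
    function(a) { a$solubility_class <- "poorly"; a },
    function(a) { a$solubility_class <- "insoluble"; a },
    function(a) { a$cyp3a4_inhibition <- TRUE; a },
    function(a) { a$pgp_interaction <- TRUE; a }
  )) {
    ann <- tweak(benign_annotation("t"))
    res <- run_cascade(clean_library("t"), ann)
    expect_equal(res$records$step, 2L)
  }
})

test_that("strict-and step 2 only fires when every clause holds", {
  ann <- benign_annotation("t")
  ann$solubility_class <- "poorly"
  cfg <- cascade_config(step2_strict_and = TRUE)
  res <- run_cascade(clean_library("t"), ann, cfg)
  expect_equal(res$records$outcome, "retained")
})

test_that("missing annotation fields never eliminate and leave a warning", {
  ann <- benign_annotation("t")
  ann$cramer_class <- NA_character_
  ann$mutagenicity <- TRUE
  ann$overall_druglikeness <- 0.5
  res <- run_cascade(clean_library("t"), ann)
  expect_equal(res$records$outcome, "retained")
  expect_true(any(grepl("cramer_class",
                        unlist(res$records$warnings))))
})

test_that("empty libraries warn and return an empty result", {
  expect_warning(
    res <- run_cascade(tibble::tibble(id = character(),
                                      smiles = character()),
                       benign_annotation(character())),
    "empty"
  )
  expect_equal(nrow(res$records), 0)
})

test_that("cascade outcomes are conserved and first-match", {
  fx <- gen_library(fixture_spec(n_compounds = 30, n_retained = 6,
                                 step_quotas = c(`1` = 5, `2` = 4, `3` = 4,
                                                 `4` = 3, `5` = 2, `6` = 2,
                                                 `7` = 1, `8` = 1, `9` = 1,
                                                 `10` = 1),
                                 seed = 7))
  res <- run_cascade(fx$compounds, fx$annotations)
  rec <- res$records
  expect_equal(sum(rec$outcome == "retained") +
                 sum(rec$outcome == "eliminated"), nrow(rec))
  s <- res$summary
  step_cols <- grep("^step\\d+_eliminated$", names(s), value = TRUE)
  expect_equal(sum(unlist(s[step_cols])), s$n_total - s$n_retained)

  # masking the steps after a compound's recorded step leaves it unchanged
  for (i in which(rec$outcome == "eliminated")[1:5]) {
    cfg <- cascade_config(steps = seq_len(rec$step[i]))
    res2 <- run_cascade(fx$compounds, fx$annotations, cfg)
    expect_equal(res2$records$step[res2$records$id == rec$id[i]],
                 rec$step[i])
  }
})

test_that("rerunning with identical inputs is bit-identical", {
  fx <- gen_library(fixture_spec(n_compounds = 20, n_retained = 5,
                                 step_quotas = c(`1` = 5, `2` = 4, `3` = 3,
                                                 `9` = 3), seed = 3))
  r1 <- run_cascade(fx$compounds, fx$annotations)
  r2 <- run_cascade(fx$compounds, fx$annotations)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$summary, r2$summary)
})

test_that("removing a step moves its eliminations later or to retained, never earlier", {
  fx <- gen_library(fixture_spec(n_compounds = 40, n_retained = 8,
                                 step_quotas = c(`1` = 6, `2` = 5, `3` = 5,
                                                 `4` = 4, `5` = 3, `6` = 3,
                                                 `7` = 2, `8` = 2, `9` = 1,
                                                 `10` = 1), seed = 5))
  base <- run_cascade(fx$compounds, fx$annotations)$records
  drop3 <- run_cascade(fx$compounds, fx$annotations,
                       cascade_config(steps = setdiff(1:10, 3)))$records
  cmp <- dplyr::left_join(base, drop3, by = "id", suffix = c("_a", "_b"))
  moved <- cmp[!is.na(cmp$step_a) & cmp$step_a == 3, ]
  expect_true(all(is.na(moved$step_b) | moved$step_b > 3))
  others <- cmp[is.na(cmp$step_a) | cmp$step_a != 3, ]
  expect_equal(others$step_b, others$step_a)
})

test_that("cascade configuration survives a YAML round-trip", {
  cfg <- cascade_config(sa_step9 = 3.5, step2_strict_and = TRUE,
                        steps = c(1:3, 7:10))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cascade_config(cfg, f)
  back <- read_cascade_config(f)
  expect_equal(back$sa_step9, 3.5)
  expect_true(back$step2_strict_and)
  expect_equal(back$steps, c(1:3, 7:10))
  res1 <- run_cascade(clean_library("x"), benign_annotation("x"), cfg)
  res2 <- run_cascade(clean_library("x"), benign_annotation("x"), back)
  expect_identical(res1$records, res2$records)
})

test_that("tidy and glance provide broom-style views", {
  fx <- gen_library(fixture_spec(n_compounds = 12, n_retained = 9,
                                 step_quotas = c(`1` = 1, `3` = 1, `9` = 1),
                                 seed = 9))
  res <- run_cascade(fx$compounds, fx$annotations)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("id", "outcome", "step", "clauses"))
  expect_equal(nrow(td), 12)
  gl <- glance(res)
  expect_equal(gl$n_total, 12)
  expect_equal(gl$n_retained, 9)
  plt <- ggplot2::autoplot(res)
  expect_s3_class(plt, "ggplot")
})
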