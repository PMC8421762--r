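test_that("recoding maps special and top codes and is idempotent", {
  tbl <- tiny_table(rbind(c(0, 3, 7), c(8, 2, NA), c(1, 2, 0)),
                    labels = c(1, 0, 1))
  rec <- recode_item_codes(tbl)
  expect_equal(unname(as.matrix(rec[item_ids(rec)])),
               rbind(c(0L, 2L, 0L), c(0L, 2L, NA), c(1L, 2L, 0L)))
  # idempotent, image restricted to {0,1,2,NA}
  rec2 <- recode_item_codes(rec)
  expect_identical(as.data.frame(rec2), as.data.frame(rec))
  vals <- unlist(rec[item_ids(rec)])
  expect_true(all(is.na(vals) | vals %in% 0:2))
})

test_that("invalid codes are rejected with subject and item named", {
  tbl <- tiny_table(rbind(c(0, 5), c(1, 2)), labels = c(1, 0))
  expect_error(recode_item_codes(tbl), "IT02")
  expect_error(recode_item_codes(tbl), "s001")
})

test_that("algorithm-item selection keeps all ADOS and non-D ADI-R algorithm items", {
  ados <- item_defs(sprintf("AD%02d", 1:31), instrument = "ADOS")
  # 93 ADI-R items; 37 algorithm non-D, 5 algorithm domain-D, rest off-algorithm
  adir <- item_defs(sprintf("AI%02d", 1:93), instrument = "ADIR",
                    in_algorithm = c(rep(TRUE, 42), rep(FALSE, 51)),
                    domain_tag = c(rep(c("A", "B", "C"), length.out = 37),
                                   rep("D", 5), rep(NA, 51)))
  defs <- rbind(ados, adir)
  n <- 5
  codes <- matrix(0L, n, nrow(defs), dimnames = list(NULL, defs$item_id))
  tbl <- tiny_table(codes, labels = c(1, 1, 0, 0, 1), items = defs)
  out <- select_algorithm_items(tbl)
  expect_equal(length(item_ids(out)), 68)           # 31 ADOS + 37 ADI-R
  expect_true(all(sprintf("AD%02d", 1:31) %in% item_ids(out)))
  expect_false(any(item_info(out)$domain_tag %in% "D"))

  # ADOS-only table is unchanged
  tbl_ados <- tiny_table(codes[, 1:31], labels = c(1, 1, 0, 0, 1),
                         items = ados)
  expect_identical(item_ids(select_algorithm_items(tbl_ados)),
                   item_ids(tbl_ados))

  # 39 algorithm items of which 2 are domain D -> 37 retained
  adir2 <- item_defs(sprintf("B%02d", 1:39), instrument = "ADIR",
                     in_algorithm = TRUE,
                     domain_tag = c(rep("A", 20), rep("D", 2), rep("B", 17)))
  tbl2 <- tiny_table(matrix(0L, 3, 39,
                            dimnames = list(NULL, adir2$item_id)),
                     labels = c(1, 0, 1), items = adir2)
  expect_equal(length(item_ids(select_algorithm_items(tbl2))), 37)

  # missing algorithm metadata on an ADI-R item is an error
  adir3 <- item_defs("AIX", instrument = "ADIR", in_algorithm = NA)
  tbl3 <- tiny_table(matrix(0L, 2, 1, dimnames = list(NULL, "AIX")),
                     labels = c(1, 0), items = adir3)
  expect_error(select_algorithm_items(tbl3), "AIX")
})

test_that("delimited I/O round-trips tables including missing and special codes", {
  tbl <- tiny_table(rbind(c(0, 3, 7), c(8, NA, 2), c(1, 2, NA)),
                    labels = c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_item_table(tbl, path)
  back <- read_item_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tbl))

  # string labels mapped per config
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_item_table(tbl, path2,
                   label_values = c(positive = "ASD", negative = "non-ASD"))
  txt <- readLines(path2)
  expect_true(any(grepl("ASD", txt)))
  back2 <- read_item_table(path2,
                           label_values = c(positive = "ASD",
                                            negative = "non-ASD"))
  expect_identical(back2$label, tbl$label)
  expect_error(read_item_table(path2), "Unmapped label")
})

test_that("reading rejects undeclared item columns", {
  tbl <- tiny_table(rbind(c(0, 1), c(1, 2)), labels = c(1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_item_table(tbl, path)
  schema <- item_defs("IT01")
  expect_error(read_item_table(path, items = schema), "IT02")
})

test_that("item schema sidecars round-trip in YAML and JSON", {
  defs <- item_defs(c("QSOV", "RECCON", "HANDFM"),
                    instrument = c("ADOS", "ADIR", "ADIR"),
                    in_algorithm = TRUE,
                    domain_tag = c(NA, "B", "C"))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_item_schema(defs, path)
    expect_equal(as.data.frame(read_item_schema(path)), as.data.frame(defs))
  }
})

test_that("stratified split preserves prevalence and is deterministic", {
  spec <- cohort_spec(item_defs(c("A", "B")), n_subjects = 1000,
                      prevalence = 0.46, exact_prevalence = TRUE, seed = 3)
  tbl <- generate_cohort(spec)$table
  sp <- train_validation_split(tbl, 0.25, seed = 9)
  expect_equal(nrow(sp$validation), 250)
  expect_equal(sum(sp$validation$label), 115, tolerance = 0)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$subject_id, sp$validation$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$validation$subject_id),
                  tbl$subject_id)
  # deterministic given seed
  sp2 <- train_validation_split(tbl, 0.25, seed = 9)
  expect_identical(sp2$validation$subject_id, sp$validation$subject_id)
  # different seed, different partition
  sp3 <- train_validation_split(tbl, 0.25, seed = 10)
  expect_false(identical(sp3$validation$subject_id,
                         sp$validation$subject_id))
})

test_that("degenerate and invalid split fractions behave as specified", {
  tbl <- tiny_table(rbind(c(0, 1), c(1, 2), c(2, 0)), labels = c(1, 0, 1))
  sp <- train_validation_split(tbl, 0)
  expect_equal(nrow(sp$validation), 0)
  expect_identical(as.data.frame(sp$train), as.data.frame(tbl))
  expect_error(train_validation_split(tbl, 1), "fraction")
  expect_error(train_validation_split(tbl, -0.1), "fraction")
})

test_that("split manifests record every subject's partition", {
  spec <- cohort_spec(item_defs(c("A", "B")), n_subjects = 40, seed = 5)
  tbl <- generate_cohort(spec)$table
  sp <- train_validation_split(tbl, 0.25, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(sp, path)
  manifest <- readr::read_tsv(path, show_col_types = FALSE)
  expect_setequal(manifest$subject_id, tbl$subject_id)
  expect_equal(sum(manifest$part == "validation"), nrow(sp$validation))
})

test_that("item tables validate labels, duplicates and column coverage", {
  expect_error(item_table(data.frame(subject_id = c("a", "a"),
                                     label = c(1, 0), X = c(0, 1))),
               "Duplicate subject_id")
  expect_error(item_table(data.frame(subject_id = c("a", "b"),
                                     label = c(1, 2), X = c(0, 1))),
               "label")
  expect_error(item_table(data.frame(subject_id = "a", label = 1, X = 0),
                          items = item_defs(c("X", "Y"))),
               "Y")
})
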