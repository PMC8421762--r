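test_that("forest encoding keeps every subject and uses the sentinel", {
  tbl <- tiny_table(rbind(c(0, NA), c(2, 1), c(NA, 2), c(1, 0)),
                    labels = c(1, 0, 1, 0))
  enc <- encode_for_forest(tbl)
  expect_equal(nrow(enc$x), 4)
  expect_equal(enc$x[[2]][1], -1)
  expect_equal(enc$x[[1]][3], -1)
  expect_identical(levels(enc$y), c("neg", "pos"))

  # no-missing table encodes identically to its codes
  tbl2 <- tiny_table(rbind(c(0, 1), c(2, 1)), labels = c(1, 0))
  expect_equal(unname(as.matrix(encode_for_forest(tbl2)$x)),
               rbind(c(0L, 1L), c(2L, 1L)))

  # un-recoded codes are refused with a pointer to recoding
  tbl3 <- tiny_table(rbind(c(0, 7), c(1, 2)), labels = c(1, 0))
  expect_error(encode_for_forest(tbl3), "recode_item_codes")
})

test_that("encoding follows schema order, not physical column order", {
  defs <- item_defs(c("B", "A"))
  d <- data.frame(subject_id = c("x", "y"), label = c(1L, 0L),
                  A = c(0L, 1L), B = c(2L, 0L))
  tbl <- item_table(d, defs)
  expect_identical(colnames(encode_for_forest(tbl)$x), c("B", "A"))
})

test_that("one importance run is produced per configured run", {
  spec <- cohort_spec(item_defs(c("A", "B", "C")), n_subjects = 120,
                      informative = c(A = 1.5), seed = 7)
  tbl <- recode_item_codes(generate_cohort(spec)$table)
  runs <- run_cv_importance(tbl, forest_config(n_trees = 30, n_runs = 1,
                                               n_folds = 4, seed = 2))
  expect_equal(unique(runs$run), 1)
  expect_setequal(runs$item_id, c("A", "B", "C"))
  # ranks form a permutation within the run
  expect_setequal(runs$rank, 1:3)
})

test_that("importance runs are deterministic given the seed", {
  spec <- cohort_spec(item_defs(c("A", "B", "C", "D")), n_subjects = 120,
                      informative = c(A = 1.5), missing_rate = 0.1, seed = 8)
  tbl <- recode_item_codes(generate_cohort(spec)$table)
  cfg <- test_config(seed = 5)
  expect_identical(run_cv_importance(tbl, cfg), run_cv_importance(tbl, cfg))
})

test_that("a strongly planted item dominates the per-run rankings", {
  defs <- item_defs(sprintf("I%02d", 1:10))
  spec <- cohort_spec(defs, n_subjects = 1000,
                      informative = c(I03 = 2), missing_rate = 0.05,
                      seed = 9)
  tbl <- recode_item_codes(generate_cohort(spec)$table)
  runs <- run_cv_importance(tbl, forest_config(n_trees = 100, n_runs = 10,
                                               n_folds = 10, n_perm = 3,
                                               seed = 13))
  top <- runs |> dplyr::filter(item_id == "I03")
  expect_gte(mean(top$rank == 1), 0.95)
})

test_that("aggregation averages ranks with importance tie-breaks", {
  runs <- tibble::tibble(
    run = rep(1:2, each = 3),
    item_id = rep(c("A", "B", "C"), 2),
    importance = c(0.30, 0.22, 0.01, 0.18, 0.30, 0.02),
    rank = c(1L, 2L, 3L, 2L, 1L, 3L)
  )
  agg <- aggregate_ranking(runs)
  # A and B tie at mean rank 1.5; B's mean importance 0.26 beats A's 0.24
  expect_equal(agg$item_id, c("B", "A", "C"))
  expect_equal(agg$mean_rank, c(1.5, 1.5, 3))
})

test_that("aggregating identical runs reproduces their order; singleton works", {
  one <- tibble::tibble(run = 1L, item_id = c("X", "Y"),
                        importance = c(0.2, 0.1), rank = c(1L, 2L))
  two <- dplyr::bind_rows(one, dplyr::mutate(one, run = 2L))
  expect_equal(aggregate_ranking(two)$item_id, c("X", "Y"))
  single <- tibble::tibble(run = 1L, item_id = "Z", importance = 0.1,
                           rank = 1L)
  agg <- aggregate_ranking(single)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mean_rank, 1)
  # inconsistent item sets across runs are rejected
  bad <- dplyr::bind_rows(one, tibble::tibble(run = 2L, item_id = "Q",
                                              importance = 0.1, rank = 1L))
  expect_error(aggregate_ranking(bad), "inconsistent")
})

test_that("the aggregated ranking is invariant to input column order", {
  defs <- item_defs(c("A", "B", "C", "D", "E"))
  spec <- cohort_spec(defs, n_subjects = 200,
                      informative = c(B = 1.5, D = 1.0), seed = 17)
  tbl <- recode_item_codes(generate_cohort(spec)$table)
  cfg <- test_config(seed = 3)
  agg1 <- aggregate_ranking(run_cv_importance(tbl, cfg))

  # same data, physically shuffled item columns, same schema
  d <- as.data.frame(tbl)
  shuffled <- d[c("subject_id", "label", "E", "C", "A", "D", "B")]
  tbl2 <- item_table(shuffled, item_info(tbl))
  agg2 <- aggregate_ranking(run_cv_importance(tbl2, cfg))
  expect_equal(as.data.frame(agg1), as.data.frame(agg2))
})

test_that("planted items concentrate at the top of the aggregated ranking", {
  defs <- item_defs(sprintf("I%02d", 1:12))
  spec <- cohort_spec(defs, n_subjects = 1000,
                      informative = c(I02 = 2, I07 = 1.8, I11 = 1.6),
                      missing_rate = 0.05, special_code_rate = 0.03,
                      seed = 19)
  tbl <- recode_item_codes(generate_cohort(spec)$table)
  agg <- aggregate_ranking(run_cv_importance(
    tbl, forest_config(n_trees = 100, n_runs = 6, n_folds = 6, n_perm = 3,
                       seed = 23)))
  expect_true(all(c("I02", "I07", "I11") %in% agg$item_id[1:6]))
})
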