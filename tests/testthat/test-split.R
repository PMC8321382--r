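test_that("test split reproduces the published per-class ceiling counts", {
  ds <- make_count_dataset(cric_counts())
  sp <- split_test(ds, 0.2, seed = 42)
  expect_equal(dataset_counts(sp$test),
               c(NILM = 173L, `ASC-US` = 58L, LSIL = 120L, `ASC-H` = 108L,
                 HSIL = 175L, SCC = 16L))
  expect_equal(sum(dataset_counts(sp$test)), 650)
  expect_equal(dataset_counts(sp$pool), cric_pool_counts())
})

test_that("holdout counts use the ceiling rule on tiny classes", {
  ds <- make_count_dataset(c(NILM = 5, `ASC-US` = 5, LSIL = 5, `ASC-H` = 5,
                             HSIL = 5, SCC = 77))
  sp <- split_test(ds, 0.2, seed = 1)
  expect_equal(unname(dataset_counts(sp$test)["NILM"]), 1L)   # ceiling(1.0)
  expect_equal(unname(dataset_counts(sp$test)["SCC"]), 16L)   # ceiling(15.4)
  expect_equal(unname(dataset_counts(sp$pool)["SCC"]), 61L)
})

test_that("splits partition the dataset and are seed-deterministic", {
  ds <- make_count_dataset(c(NILM = 30, `ASC-US` = 11, LSIL = 17,
                             `ASC-H` = 13, HSIL = 29, SCC = 7))
  a <- split_test(ds, 0.2, seed = 5)
  b <- split_test(ds, 0.2, seed = 5)
  c <- split_test(ds, 0.2, seed = 6)
  expect_identical(a$test$marks, b$test$marks)
  expect_setequal(c(a$pool$marks$mark_id, a$test$marks$mark_id),
                  ds$marks$mark_id)
  expect_length(intersect(a$pool$marks$mark_id, a$test$marks$mark_id), 0)
  # different seed: identical counts, different membership
  expect_equal(dataset_counts(a$test), dataset_counts(c$test))
  expect_false(identical(a$test$marks$mark_id, c$test$marks$mark_id))
})

test_that("empty required classes abort the split by name", {
  ds <- make_count_dataset(c(NILM = 5, HSIL = 5))
  expect_error(split_test(ds, 0.2, seed = 1), "ASC-US")
  expect_silent(split_test(ds, 0.2, seed = 1, labels = c("NILM", "HSIL")))
})

test_that("validation re-split applies the ceiling rule to balanced classes", {
  # balanced six-class pools from the published tables
  ds <- make_count_dataset(c(NILM = 10, `ASC-US` = 684, LSIL = 10,
                             `ASC-H` = 10, HSIL = 10, SCC = 671))
  tv <- split_validation(ds, 0.2, seed = 3)
  expect_equal(unname(dataset_counts(tv$validation)["SCC"]), 135L)
  expect_equal(unname(dataset_counts(tv$train)["SCC"]), 536L)
  expect_equal(unname(dataset_counts(tv$validation)["ASC-US"]), 137L)
  expect_equal(unname(dataset_counts(tv$train)["ASC-US"]), 547L)
  expect_equal(unname(dataset_counts(tv$validation)["NILM"]), 2L)  # pool 10
  expect_equal(unname(dataset_counts(tv$train)["NILM"]), 8L)
})

test_that("group_by_source keeps augmented copies of a source together", {
  pool <- make_count_dataset(c(NILM = 12, `ASC-US` = 12, LSIL = 12,
                               `ASC-H` = 12, HSIL = 12, SCC = 12))
  scheme <- class_scheme("six")
  plan <- plan_balance(setNames(rep(12L, 6), bethesda_labels()), scheme,
                       mode = "general")
  # force augmentation by unbalancing one class
  pool2 <- make_count_dataset(c(NILM = 12, `ASC-US` = 6, LSIL = 12,
                                `ASC-H` = 12, HSIL = 12, SCC = 12))
  plan2 <- plan_balance(dataset_counts(pool2), scheme, mode = "general")
  bal <- expand_pool(pool2, plan2, seed = 1)
  tv <- split_validation(bal, 0.25, seed = 2, group_by_source = TRUE)
  src_val <- unique(tv$validation$marks$source_mark)
  src_train <- unique(tv$train$marks$source_mark)
  expect_length(intersect(src_val, src_train), 0)
})
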