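test_that("literal plans reproduce the published per-class totals", {
  pools <- cric_pool_counts()
  p6 <- plan_balance(pools, class_scheme("six"), mode = "paper")
  expect_equal(planned_sizes(p6),
               c(NILM = 689L, `ASC-US` = 684L, LSIL = 698L, `ASC-H` = 698L,
                 HSIL = 699L, SCC = 671L))
  p3 <- plan_balance(pools, class_scheme("three"), mode = "paper")
  expect_equal(planned_sizes(p3),
               c(NILM = 2067L, `ASC-US` = 1042L, LSIL = 1056L,
                 `ASC-H` = 698L, HSIL = 699L, SCC = 671L))
  # the hand-made three-class low-grade plans overshoot half the group
  expect_gt(planned_sizes(p3)[["ASC-US"]], 2068 / 2)
  p2 <- plan_balance(pools, class_scheme("two"), mode = "paper")
  expect_equal(planned_sizes(p2)[["NILM"]], 3445L)
  altered <- setdiff(bethesda_labels(), "NILM")
  expect_equal(sum(planned_sizes(p2)[altered]), 3450L)
})

test_that("literal plans refuse foreign pool counts", {
  wrong <- cric_pool_counts(); wrong[["SCC"]] <- 60L
  expect_error(plan_balance(wrong, class_scheme("six"), mode = "paper"),
               "reference pool counts")
})

test_that("general plans hit the reference target exactly", {
  pools <- cric_pool_counts()
  g6 <- plan_balance(pools, class_scheme("six"), mode = "general")
  expect_equal(unname(planned_sizes(g6)), rep(699L, 6))
  # SCC 61 -> 699: e = 638, q = 10, r = 28 (28 sources get 11, 33 get 10)
  scc <- g6$entries[g6$entries$class == "SCC", ]
  expect_equal(sort(scc$subset_size), c(28L, 33L))
  expect_equal(sort(scc$transforms_each), c(10L, 11L))
  expect_equal(sum(scc$subset_size * scc$transforms_each) + 61L, 699L)
  # a class already at target is untouched
  expect_false("HSIL" %in% g6$entries$class)
  g3 <- plan_balance(pools, class_scheme("three"), mode = "general")
  sizes <- planned_sizes(g3)
  groups <- scheme_groups(class_scheme("three"))
  expect_equal(unname(sizes[groups[["high-grade"]]]), rep(699L, 3))
  expect_equal(sum(sizes[groups[["low-grade"]]]), 3 * 699L)
  expect_equal(sizes[["NILM"]], 3 * 699L)
})

test_that("expansion realizes planned counts with full provenance", {
  pools <- cric_pool_counts()
  ds <- make_count_dataset(pools)
  for (nm in c("six", "three", "two")) {
    plan <- plan_balance(pools, class_scheme(nm), mode = "paper")
    bal <- expand_pool(ds, plan, seed = 9)
    expect_equal(dataset_counts(bal), planned_sizes(plan))
    # conservation: every original sample survives
    expect_true(all(ds$marks$mark_id %in% bal$marks$mark_id))
  }
  plan6 <- plan_balance(pools, class_scheme("six"), mode = "paper")
  bal6 <- expand_pool(ds, plan6, seed = 9)
  # SCC: all 10 tags per source, so each source contributes exactly 11
  scc <- bal6$marks[bal6$marks$label == "SCC", ]
  per_src <- table(scc$source_mark)
  expect_true(all(per_src == 11))
  tags_per_src <- tapply(scc$transform_tag, scc$source_mark,
                         function(tg) sort(tg))
  expect_true(all(vapply(tags_per_src, function(tg)
    identical(unname(tg), sort(c("identity", aug_tags()))), logical(1))))
  # no source repeats a tag anywhere
  expect_false(any(duplicated(bal6$marks[, c("source_mark", "transform_tag")])))
})

test_that("an empty plan returns the pool unchanged", {
  counts <- setNames(rep(10L, 6), bethesda_labels())
  ds <- make_count_dataset(counts)
  plan <- plan_balance(counts, class_scheme("six"), mode = "general")
  expect_equal(nrow(plan$entries), 0)
  bal <- expand_pool(ds, plan, seed = 1)
  expect_identical(bal$marks, ds$marks)
})

test_that("expansion rejects a mismatched pool", {
  plan <- plan_balance(cric_pool_counts(), class_scheme("six"),
                       mode = "paper")
  small <- make_count_dataset(setNames(rep(5L, 6), bethesda_labels()))
  expect_error(expand_pool(small, plan, seed = 1), "pool counts")
})

test_that("expansion is seed-deterministic", {
  counts <- c(NILM = 20L, `ASC-US` = 7L, LSIL = 12L, `ASC-H` = 9L,
              HSIL = 20L, SCC = 5L)
  ds <- make_count_dataset(counts)
  plan <- plan_balance(counts, class_scheme("six"), mode = "general")
  a <- expand_pool(ds, plan, seed = 4)
  b <- expand_pool(ds, plan, seed = 4)
  c <- expand_pool(ds, plan, seed = 5)
  expect_identical(a$marks, b$marks)
  expect_equal(dataset_counts(c), dataset_counts(a))
  expect_false(identical(a$marks$mark_id, c$marks$mark_id))
})
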