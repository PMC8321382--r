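make_pred <- function(name, predicted, classes) {
  n <- length(predicted)
  scores <- t(vapply(predicted, function(p)
    as.numeric(classes == p), numeric(length(classes))))
  colnames(scores) <- classes
  structure(list(model_name = name, classes = classes, scores = scores,
                 predicted = predicted,
                 mark_id = as.character(seq_len(n))),
            class = "cyto_predictions")
}

test_that("member selection is top-k by recall with a leading tiebreaker", {
  spec <- select_members(c(A = 0.9, B = 0.8, C = 0.7, D = 0.6), k = 3,
                         seed = 1)
  expect_equal(spec$members, c("A", "B", "C"))
  expect_equal(spec$tiebreaker, "A")
  expect_error(select_members(c(A = 0.9), k = 3), "exceeds")
})

test_that("ties at the selection cut are broken by seed among the tied", {
  recalls <- c(A = 0.95, B = 0.95, C = 0.95, D = 0.94)
  for (s in 1:5) {
    spec <- select_members(recalls, k = 3, seed = s)
    expect_false("D" %in% spec$members)
    expect_true(all(recalls[spec$members] >=
                      max(recalls[setdiff(names(recalls), spec$members)])))
  }
  # six-way tie: different seeds may pick different members, but the
  # member-recall multiset is invariant
  tied <- setNames(rep(0.9, 6), LETTERS[1:6])
  s1 <- select_members(tied, k = 3, seed = 1)
  s2 <- select_members(tied, k = 3, seed = 2)
  expect_equal(sort(unname(s1$recalls)), sort(unname(s2$recalls)))
})

test_that("majority vote follows the published rule", {
  cls <- c("NILM", "LSIL", "HSIL")
  spec <- select_members(c(m1 = 0.9, m2 = 0.8, m3 = 0.7), k = 3, seed = 1)
  preds <- list(m1 = make_pred("m1", c("HSIL", "NILM", "NILM"), cls),
                m2 = make_pred("m2", c("HSIL", "LSIL", "NILM"), cls),
                m3 = make_pred("m3", c("LSIL", "HSIL", "NILM"), cls))
  out <- ensemble_vote(spec, preds)
  # sample 1: strict majority HSIL; sample 2: all disagree -> best member;
  # sample 3: unanimity
  expect_equal(out$predicted, c("HSIL", "NILM", "NILM"))
})

test_that("vote decisions match brute force on every three-voter combination", {
  cls6 <- bethesda_labels()
  spec <- select_members(c(m1 = 0.9, m2 = 0.8, m3 = 0.7), k = 3, seed = 1)
  combos <- expand.grid(v1 = cls6, v2 = cls6, v3 = cls6,
                        stringsAsFactors = FALSE)
  preds <- list(m1 = make_pred("m1", combos$v1, cls6),
                m2 = make_pred("m2", combos$v2, cls6),
                m3 = make_pred("m3", combos$v3, cls6))
  out <- ensemble_vote(spec, preds)
  oracle <- vapply(seq_len(nrow(combos)), function(i)
    brute_vote(c(combos$v1[i], combos$v2[i], combos$v3[i]), cls6),
    character(1))
  expect_equal(nrow(combos), 216)
  expect_equal(out$predicted, oracle)

  # two-class scheme: all 8 combinations, a 3-way tie is impossible
  cls2 <- c("normal", "altered")
  combos2 <- expand.grid(v1 = cls2, v2 = cls2, v3 = cls2,
                         stringsAsFactors = FALSE)
  preds2 <- list(m1 = make_pred("m1", combos2$v1, cls2),
                 m2 = make_pred("m2", combos2$v2, cls2),
                 m3 = make_pred("m3", combos2$v3, cls2))
  out2 <- ensemble_vote(spec, preds2)
  for (i in 1:8) {
    votes <- c(combos2$v1[i], combos2$v2[i], combos2$v3[i])
    expect_gte(max(table(votes)), 2)               # never all-different
    expect_equal(out2$predicted[i], brute_vote(votes, cls2))
  }
})

test_that("vote is invariant to swapping members 2 and 3", {
  cls <- bethesda_labels()
  spec <- select_members(c(m1 = 0.9, m2 = 0.8, m3 = 0.7), k = 3, seed = 1)
  set.seed(12)
  preds <- lapply(setNames(c("m1", "m2", "m3"), c("m1", "m2", "m3")),
                  function(nm) make_pred(nm, sample(cls, 50, TRUE), cls))
  out_a <- ensemble_vote(spec, preds)
  swapped <- preds
  swapped$m2 <- make_pred("m2", preds$m3$predicted, cls)
  swapped$m3 <- make_pred("m3", preds$m2$predicted, cls)
  out_b <- ensemble_vote(spec, swapped)
  expect_equal(out_a$predicted, out_b$predicted)

  # unanimity passes through unchanged
  same <- lapply(setNames(c("m1", "m2", "m3"), c("m1", "m2", "m3")),
                 function(nm) make_pred(nm, preds$m1$predicted, cls))
  expect_equal(ensemble_vote(spec, same)$predicted, preds$m1$predicted)
})

test_that("misaligned prediction sets are rejected", {
  cls <- c("normal", "altered")
  spec <- select_members(c(m1 = 0.9, m2 = 0.8, m3 = 0.7), k = 3, seed = 1)
  preds <- list(m1 = make_pred("m1", c("normal", "altered"), cls),
                m2 = make_pred("m2", c("normal", "altered"), cls),
                m3 = make_pred("m3", c("normal", "altered"), cls))
  preds$m3$mark_id <- rev(preds$m3$mark_id)
  expect_error(ensemble_vote(spec, preds), "not aligned")
})
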