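# Small separable fixture: two "classes" of blobs differing in radius.
make_blob_inputs <- function(n_per_class, size = 32, radii = c(4, 9),
                             noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(0, c(n, size, size))
    y <- rep(c("normal", "altered"), each = n_per_class)
    ctr <- size / 2
    d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
    for (i in seq_len(n)) {
      r <- radii[(y[i] == "altered") + 1] + rnorm(1, 0, 0.3)
      x[i, , ] <- pmin(pmax(0.8 - 0.5 * (d < r) +
                              rnorm(size^2, 0, noise), 0), 1)
    }
    list(x = x, y = y)
  })
}

test_that("the head produces probability rows over the target classes", {
  m <- build_model("tiny", classes = bethesda_labels(), seed = 2)
  expect_equal(m$dropout_rate, 0.2)   # default head dropout
  x <- array(runif(5 * 32 * 32), c(5, 32, 32))
  p <- predict(m, x)
  expect_equal(dim(p$scores), c(5, 6))
  expect_equal(rowSums(p$scores), rep(1, 5), tolerance = 1e-6)
  expect_length(p$predicted, 5)
})

test_that("inference is deterministic regardless of dropout", {
  m <- build_model("tiny", classes = c("normal", "altered"),
                   dropout_rate = 0.2, seed = 3)
  dat <- make_blob_inputs(20)
  m <- train_model(m, dat$x, dat$y, epochs = 3, seed = 4)
  p1 <- predict(m, dat$x)
  p2 <- predict(m, dat$x)
  expect_identical(p1$scores, p2$scores)
})

test_that("training improves recall on an overlapping-blob problem", {
  # hard enough that epoch 1 is under-trained, separable enough to learn
  dat <- make_blob_inputs(100, radii = c(5, 5.8), noise = 0.4)
  m <- build_model("tiny", classes = c("normal", "altered"), seed = 5)
  m <- train_model(m, dat$x, dat$y, epochs = 10, batch_size = 32,
                   lr = 1e-4, seed = 6)
  h <- m$history
  expect_equal(nrow(h), 10)
  expect_gt(max(h$recall), h$recall[1])
  expect_gte(h$recall[which.max(h$recall)], 0.8)

  # an easy wide-gap problem is learned to (near-)perfection
  easy <- make_blob_inputs(50)
  m2 <- build_model("tiny", classes = c("normal", "altered"), seed = 5)
  m2 <- train_model(m2, easy$x, easy$y, epochs = 5, seed = 6)
  expect_gte(max(m2$history$recall), 0.97)
  expect_true(all(c("epoch", "loss", "recall", "val_recall") %in% names(h)))
})

test_that("training is reproducible end-to-end under fixed seeds", {
  dat <- make_blob_inputs(30)
  fit <- function() {
    m <- build_model("tiny", classes = c("normal", "altered"), seed = 7)
    m <- train_model(m, dat$x, dat$y, epochs = 3, seed = 8)
    predict(m, dat$x)$scores
  }
  expect_identical(fit(), fit())
})

test_that("zero epochs is a no-op with empty history", {
  dat <- make_blob_inputs(5)
  m <- build_model("tiny", classes = c("normal", "altered"), seed = 9)
  m2 <- train_model(m, dat$x, dat$y, epochs = 0, seed = 1)
  expect_equal(m2$W, m$W)
  expect_equal(nrow(m2$history), 0)
})

test_that("degenerate inputs are rejected with clear errors", {
  dat <- make_blob_inputs(5)
  m <- build_model("tiny", classes = c("normal", "altered"), seed = 1)
  expect_error(train_model(m, dat$x, rep("normal", dim(dat$x)[1])),
               "absent from the training set")
  expect_error(build_model("resnet", classes = c("a", "b")),
               "registered: tiny")
  expect_error(predict(m, array(0, c(2, 16, 16))), "expects 32x32")
})

test_that("the head is backbone-agnostic: structure follows the registry", {
  for (cls in list(c("normal", "altered"), bethesda_labels())) {
    m <- build_model("tiny", classes = cls, seed = 1)
    expect_equal(length(m$filters), length(m$channels))
    expect_equal(dim(m$W), c(m$fdim, length(cls)))
    expect_equal(m$fdim,
                 (m$input_size / 2^length(m$channels))^2 *
                   m$channels[length(m$channels)])
  }
})
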