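#' Available classifier backbones
#'
#' The feature-extractor registry. The built-in `"tiny"` backbone is three
#' convolution blocks (3x3 kernels, ReLU, 2x2 average pooling) with fixed,
#' seed-initialized filters; only the classification head is trained, the
#' standard frozen-feature transfer-learning setup. It needs no external
#' weights and runs on a single CPU.
#'
#' @return Named list of backbone definitions (`channels` per block).
#' @export
backbone_registry <- function() {
  list(tiny = list(channels = c(8L, 8L, 8L)))
}

#' Build a classifier: backbone plus dropout/softmax head
#'
#' The model is the fixed convolutional backbone followed by the trained
#' head: flatten, dropout (default rate 0.2), and a dense softmax layer
#' with one output per target class. The head is fitted with the Adam
#' optimizer under a categorical cross-entropy loss, and macro recall is
#' the monitored metric.
#'
#' @param backbone Backbone name; see [backbone_registry()].
#' @param classes Character vector of target class names, in display order.
#' @param dropout_rate Head dropout rate in \[0,1). Default 0.2.
#' @param input_size Side length the crops are resized to before the
#'   backbone (bilinear); must be a multiple of 8. Default 32.
#' @param seed Seed for the backbone filter initialization; different
#'   seeds give different (diverse) ensemble members.
#' @param name Model name used in reports; defaults to
#'   `"<backbone>-s<seed>"`.
#' @return An object of class `cyto_model`.
#' @export
build_model <- function(backbone = "tiny", classes, dropout_rate = 0.2,
                        input_size = 32L, seed = 1L, name = NULL) {
  reg <- backbone_registry()
  if (!backbone %in% names(reg))
    stop("unknown backbone '", backbone, "'; registered: ",
         paste(names(reg), collapse = ", "))
  stopifnot(length(classes) >= 2, dropout_rate >= 0, dropout_rate < 1,
            input_size %% 8 == 0)
  channels <- reg[[backbone]]$channels
  filters <- with_seed(seed, {
    cin <- 1L
    lapply(channels, function(cout) {
      w <- array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                 c(3, 3, cin, cout))
      cin <<- cout
      list(w = w, b = rep(0, cout))
    })
  })
  fdim <- as.integer((input_size / 2^length(channels))^2 * channels[length(channels)])
  structure(list(
    name = name %||% sprintf("%s-s%d", backbone, as.integer(seed)),
    backbone = backbone, channels = channels, filters = filters,
    input_size = as.integer(input_size), dropout_rate = dropout_rate,
    classes = as.character(classes), fdim = fdim,
    W = matrix(0, fdim, length(classes)), b = rep(0, length(classes)),
    feat_center = NULL, feat_scale = NULL,
    trained = FALSE, history = NULL
  ), class = "cyto_model")
}

#' @export
print.cyto_model <- function(x, ...) {
  cat(sprintf("<cyto_model> %s: %s backbone (%s channels), input %dx%d,\n",
              x$name, x$backbone, paste(x$channels, collapse = "-"),
              x$input_size, x$input_size))
  cat(sprintf("  head: flatten(%d) -> dropout(%.2f) -> dense softmax(%d: %s)\n",
              x$fdim, x$dropout_rate, length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat("  trained:", x$trained,
      if (x$trained) sprintf("(%d epochs)", nrow(x$history)) else "", "\n")
  invisible(x)
}

# --- backbone forward pass -------------------------------------------------

# 'same' 3x3 convolution over a batch array [n, h, w, cin].
conv3x3 <- function(a, w, b) {
  d <- dim(a)
  n <- d[1]; h <- d[2]; wd <- d[3]; cin <- d[4]; cout <- dim(w)[4]
  apad <- array(0, c(n, h + 2, wd + 2, cin))
  apad[, 2:(h + 1), 2:(wd + 1), ] <- a
  out <- array(0, c(n, h, wd, cout))
  for (co in seq_len(cout)) {
    acc <- array(b[co], c(n, h, wd))
    for (ci in seq_len(cin))
      for (dy in 0:2)
        for (dx in 0:2)
          acc <- acc + w[dy + 1, dx + 1, ci, co] *
            apad[, (1 + dy):(h + dy), (1 + dx):(wd + dx), ci]
    out[, , , co] <- acc
  }
  out
}

avg_pool2 <- function(a) {
  d <- dim(a)
  h <- d[2]; w <- d[3]
  io <- seq(1, h, by = 2); ie <- seq(2, h, by = 2)
  jo <- seq(1, w, by = 2); je <- seq(2, w, by = 2)
  (a[, io, jo, , drop = FALSE] + a[, ie, jo, , drop = FALSE] +
   a[, io, je, , drop = FALSE] + a[, ie, je, , drop = FALSE]) / 4
}

# Flattened backbone features for a batch [n, s, s]; chunked to bound memory.
backbone_features <- function(model, x, chunk = 512L) {
  n <- dim(x)[1]
  out <- matrix(0, n, model$fdim)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    a <- array(x[lo:hi, , , drop = FALSE],
               c(hi - lo + 1L, model$input_size, model$input_size, 1L))
    for (blk in model$filters) {
      a <- conv3x3(a, blk$w, blk$b)
      a[a < 0] <- 0
      a <- avg_pool2(a)
    }
    out[lo:hi, ] <- matrix(a, hi - lo + 1L)
  }
  out
}

# --- head ------------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the classification head of a model
#'
#' Minibatch Adam on the categorical cross-entropy of the softmax head,
#' with inverted dropout on the flattened features. Features are
#' standardized using training-set statistics (stored in the model).
#' Training history records per-epoch loss and macro recall on the
#' training set, plus validation macro recall when a validation set is
#' given; early stopping restores the head with the best validation
#' recall.
#'
#' @param model A [build_model()] result.
#' @param x Numeric array `[n, s, s]` of resized crops (see
#'   [prepare_inputs()]).
#' @param y Character vector of target class labels, length `n`.
#' @param validation Optional list with elements `x` and `y`.
#' @param epochs Training epochs (0 = no-op). Default 30.
#' @param batch_size Minibatch size. Default 32.
#' @param lr Adam learning rate. Default 1e-3.
#' @param patience Early-stopping patience on validation recall. Default 5.
#' @param seed Seed for shuffling and dropout masks.
#' @return The fitted `cyto_model`, with `$history` a data.frame of
#'   `epoch`, `loss`, `recall`, `val_recall`.
#' @export
train_model <- function(model, x, y, validation = NULL, epochs = 30,
                        batch_size = 32, lr = 1e-3, patience = 5,
                        seed = 1L) {
  stopifnot(inherits(model, "cyto_model"))
  if (length(y) != dim(x)[1]) stop("x and y lengths differ")
  absent <- setdiff(model$classes, unique(y))
  if (length(absent) > 0)
    stop("class(es) absent from the training set: ",
         paste(absent, collapse = ", "))
  bad <- setdiff(unique(y), model$classes)
  if (length(bad) > 0)
    stop("training labels outside the model's classes: ",
         paste(bad, collapse = ", "))
  model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                              recall = numeric(0), val_recall = numeric(0))
  if (epochs == 0) return(model)

  f <- backbone_features(model, x)
  model$feat_center <- colMeans(f)
  model$feat_scale <- pmax(apply(f, 2, stats::sd), 1e-8)
  f <- scale(f, model$feat_center, model$feat_scale)
  fv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    fv <- scale(backbone_features(model, validation$x),
                model$feat_center, model$feat_scale)
    yv <- validation$y
  }
  K <- length(model$classes)
  n <- nrow(f)
  Y <- diag(K)[match(y, model$classes), , drop = FALSE]
  W <- model$W; b <- model$b
  mW <- vW <- 0 * W; mb <- vb <- 0 * b
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8; t <- 0
  keep <- 1 - model$dropout_rate
  best <- list(W = W, b = b, val = -Inf, epoch = 0L)
  hist <- vector("list", epochs)

  with_seed(seed, for (ep in seq_len(epochs)) {
    idx <- sample(n)
    ep_loss <- 0
    for (lo in seq(1, n, by = batch_size)) {
      bi <- idx[lo:min(lo + batch_size - 1, n)]
      fb <- f[bi, , drop = FALSE]
      if (keep < 1) {
        mask <- matrix(stats::rbinom(length(fb), 1, keep), nrow(fb)) / keep
        fb <- fb * mask
      }
      p <- softmax_rows(sweep(fb %*% W, 2, b, "+"))
      yb <- Y[bi, , drop = FALSE]
      ep_loss <- ep_loss - sum(log(pmax(rowSums(p * yb), 1e-12)))
      g <- (p - yb) / length(bi)
      gW <- crossprod(fb, g)
      gb <- colSums(g)
      t <- t + 1
      mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      W <- W - lr * (mW / (1 - b1^t)) / (sqrt(vW / (1 - b2^t)) + epsa)
      b <- b - lr * (mb / (1 - b1^t)) / (sqrt(vb / (1 - b2^t)) + epsa)
    }
    pred <- model$classes[max.col(sweep(f %*% W, 2, b, "+"),
                                  ties.method = "first")]
    rec <- mean_class_recall(y, pred, model$classes)
    val_rec <- NA_real_
    if (!is.null(fv)) {
      pv <- model$classes[max.col(sweep(fv %*% W, 2, b, "+"),
                                  ties.method = "first")]
      val_rec <- mean_class_recall(yv, pv, model$classes)
      if (val_rec > best$val) best <- list(W = W, b = b, val = val_rec, epoch = ep)
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n, recall = rec,
                             val_recall = val_rec)
    if (!is.null(fv) && ep - best$epoch >= patience) break
  })

  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (!is.null(fv) && best$epoch > 0) {
    model$W <- best$W; model$b <- best$b
  } else {
    model$W <- W; model$b <- b
  }
  model$trained <- TRUE
  model
}

# Macro recall helper used during training (cheap, no report object).
mean_class_recall <- function(truth, pred, classes) {
  mean(vapply(classes, function(cl) {
    i <- truth == cl
    if (!any(i)) return(0)
    mean(pred[i] == cl)
  }, numeric(1)))
}

#' Predict class scores for a batch of crops
#'
#' @param object A trained `cyto_model`.
#' @param x Numeric array `[n, s, s]` with `s = object$input_size`.
#' @param mark_id Optional sample identifiers carried into the result.
#' @param ... Unused.
#' @return A `cyto_predictions` object: `scores` (rows are probability
#'   vectors over `classes`), `predicted` (argmax, ties to the lowest
#'   class index), `mark_id`, `model_name`.
#' @export
predict.cyto_model <- function(object, x, mark_id = NULL, ...) {
  d <- dim(x)
  if (length(d) == 2) x <- array(x, c(1, d))
  if (dim(x)[2] != object$input_size || dim(x)[3] != object$input_size)
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 dim(x)[2], dim(x)[3], object$input_size, object$input_size))
  f <- backbone_features(object, x)
  if (!is.null(object$feat_center))
    f <- scale(f, object$feat_center, object$feat_scale)
  p <- softmax_rows(sweep(f %*% object$W, 2, object$b, "+"))
  colnames(p) <- object$classes
  structure(list(model_name = object$name, classes = object$classes,
                 scores = p,
                 predicted = object$classes[max.col(p, ties.method = "first")],
                 mark_id = mark_id %||% as.character(seq_len(nrow(p)))),
            class = "cyto_predictions")
}

#' @export
print.cyto_predictions <- function(x, ...) {
  cat(sprintf("<cyto_predictions> %s: %d samples over %d classes\n",
              x$model_name, nrow(x$scores), length(x$classes)))
  print(table(factor(x$predicted, levels = x$classes)))
  invisible(x)
}

#' Write a prediction set to CSV
#'
#' Columns: `mark_id`, `model_name`, one score column per class, and the
#' predicted label.
#'
#' @param pred A `cyto_predictions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  df <- data.frame(mark_id = pred$mark_id, model_name = pred$model_name,
                   pred$scores, predicted = pred$predicted,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
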