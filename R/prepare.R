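#' Bilinear image resize
#'
#' Separable bilinear interpolation with half-pixel center alignment,
#' implemented as two matrix products.
#'
#' @param image Numeric matrix.
#' @param height,width Output dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(image, height, width = height) {
  interp_mat <- function(n_out, n_in) {
    A <- matrix(0, n_out, n_in)
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based src coords
    lo <- floor(src)
    frac <- src - lo
    lo <- pmin(pmax(lo, 0), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    for (i in seq_len(n_out)) {
      A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - frac[i])
      A[i, hi[i] + 1] <- A[i, hi[i] + 1] + frac[i]
    }
    A
  }
  A <- interp_mat(height, nrow(image))
  B <- interp_mat(width, ncol(image))
  A %*% image %*% t(B)
}

#' Materialize model inputs for every mark of a dataset
#'
#' For each row of the (possibly augmented) marks table: crop the m-by-m
#' nucleus patch from the source image, apply the row's transform tag, and
#' resize to the model input size. The `noise_random` tag is seeded per
#' sample from `seed` and the row's `mark_id`, so preparation is
#' reproducible and independent of chunking.
#'
#' @param dataset A [cyto_dataset()] (augmented rows carry
#'   `transform_tag` and `source_mark`).
#' @param m Crop side length. Default 90.
#' @param input_size Output side length. Default 32.
#' @param seed Integer seed for stochastic transforms.
#' @param scheme Optional [class_scheme()]; when given, `y` holds target
#'   classes instead of six-class labels.
#' @param params Photometric transform parameters, see [aug_params()].
#' @return List: `x` array `[n, input_size, input_size]`, `y` character
#'   labels, `mark_id` character vector, all in canonical dataset order.
#' @export
prepare_inputs <- function(dataset, m = 90, input_size = 32, seed = 1L,
                           scheme = NULL, params = aug_params()) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  mk <- dataset$marks
  n <- nrow(mk)
  x <- array(0, c(n, input_size, input_size))
  cache_id <- ""
  img <- NULL
  for (i in seq_len(n)) {
    if (mk$image_id[i] != cache_id) {
      img <- get_image(dataset, mk$image_id[i])
      cache_id <- mk$image_id[i]
    }
    p <- crop_patch(img, mk$x[i], mk$y[i], m)
    tag <- mk$transform_tag[i]
    if (tag != "identity")
      p <- apply_aug(p, tag,
                     seed = sub_seed(seed, string_seed(mk$mark_id[i])),
                     params = params)
    x[i, , ] <- resize_bilinear(p, input_size)
  }
  y <- if (is.null(scheme)) mk$label else map_label(scheme, mk$label)
  list(x = x, y = y, mark_id = mk$mark_id)
}

# Stable small integer hash of a string (order-independent seeding).
string_seed <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * (seq_along(v) %% 31 + 1)) %% 1000003)
}
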