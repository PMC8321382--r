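#' The ten augmentation transforms, in canonical order
#'
#' Class balancing draws from ten label-preserving transforms: the three
#' non-trivial rotations, the mirrored versions of all four rotations, and
#' three photometric variants (additive random noise, a total-variation
#' smoothed copy, and a bilateral-filtered copy). Together with `identity`,
#' the seven geometric tags realize the dihedral group of the square; the
#' photometric tags perturb intensities without moving pixels.
#'
#' @return Character vector of the 10 transform tags.
#' @export
aug_tags <- function() {
  c("rot90", "rot180", "rot270",
    "mirror", "mirror90", "mirror180", "mirror270",
    "noise_random", "noise_tv", "noise_bilateral")
}

#' Default parameters of the photometric transforms
#'
#' `noise_sigma` is the standard deviation of the additive Gaussian noise,
#' as a fraction of the \[0,1\] value range; `tv_weight` the
#' total-variation denoising weight; `bilateral_sigma_color` (fraction of
#' the value range) and `bilateral_sigma_spatial` (pixels) the bilateral
#' kernel widths.
#'
#' @return Named list of parameter defaults.
#' @export
aug_params <- function() {
  list(noise_sigma = 0.01, tv_weight = 0.1,
       bilateral_sigma_color = 0.05, bilateral_sigma_spatial = 3)
}

#' Apply one augmentation transform to a patch
#'
#' Geometric tags are exact pixel permutations; photometric tags keep the
#' patch size and clip to \[0,1\]. `noise_random` is the only stochastic
#' tag and is fully determined by `seed`.
#'
#' @param patch Numeric matrix (a crop).
#' @param tag One of [aug_tags()], or `"identity"`.
#' @param seed Integer seed for `noise_random`.
#' @param params Photometric parameters, see [aug_params()].
#' @return Transformed matrix of the same dimensions.
#' @export
apply_aug <- function(patch, tag, seed = 1L, params = aug_params()) {
  stopifnot(is.matrix(patch))
  switch(tag,
    identity = patch,
    rot90 = rot_cw(patch),
    rot180 = rot_cw(rot_cw(patch)),
    rot270 = rot_cw(rot_cw(rot_cw(patch))),
    mirror = fliplr(patch),
    mirror90 = fliplr(rot_cw(patch)),
    mirror180 = fliplr(rot_cw(rot_cw(patch))),
    mirror270 = fliplr(rot_cw(rot_cw(rot_cw(patch)))),
    noise_random = with_seed(seed, clip01(patch + matrix(
      stats::rnorm(length(patch), 0, params$noise_sigma), nrow(patch)))),
    noise_tv = clip01(tv_smooth(patch, weight = params$tv_weight)),
    noise_bilateral = clip01(bilateral_smooth(
      patch, sigma_color = params$bilateral_sigma_color,
      sigma_spatial = params$bilateral_sigma_spatial)),
    stop("unknown transform tag: ", tag)
  )
}

# 90 degree clockwise rotation (pixel permutation).
rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Left-right mirror (pixel permutation).
fliplr <- function(m) m[, ncol(m):1, drop = FALSE]

#' Total-variation smoothing (Chambolle dual projection)
#'
#' Rudin-Osher-Fatemi denoising solved by Chambolle's fixed-point iteration
#' on the dual variable. Larger `weight` smooths more.
#'
#' @param image Numeric matrix.
#' @param weight Denoising weight, default 0.1.
#' @param n_iter Maximum iterations.
#' @param eps Relative energy-change stopping tolerance.
#' @return Smoothed matrix, same dimensions.
#' @export
tv_smooth <- function(image, weight = 0.1, n_iter = 50, eps = 2e-4) {
  h <- nrow(image); w <- ncol(image)
  p1 <- matrix(0, h, w); p2 <- matrix(0, h, w)
  d <- matrix(0, h, w)
  out <- image
  tau <- 1 / 4
  e_init <- 0; e_prev <- 0
  for (it in seq_len(n_iter)) {
    if (it > 1) {
      # d = -div p (adjoint of the forward-difference gradient)
      d <- -(p1 + p2)
      d[2:h, ] <- d[2:h, ] + p1[1:(h - 1), ]
      d[, 2:w] <- d[, 2:w] + p2[, 1:(w - 1)]
      out <- image + d
    }
    e <- sum(d^2)
    g1 <- matrix(0, h, w); g2 <- matrix(0, h, w)
    g1[1:(h - 1), ] <- out[2:h, ] - out[1:(h - 1), ]
    g2[, 1:(w - 1)] <- out[, 2:w] - out[, 1:(w - 1)]
    nrm <- sqrt(g1^2 + g2^2)
    e <- (e + weight * sum(nrm)) / length(image)
    nrm <- nrm * (tau / weight) + 1
    p1 <- (p1 - tau * g1) / nrm
    p2 <- (p2 - tau * g2) / nrm
    if (it == 1) e_init <- e
    else if (abs(e_prev - e) < eps * e_init) break
    e_prev <- e
  }
  out
}

#' Bilateral smoothing
#'
#' Gaussian range-and-domain filter: each pixel is replaced by a weighted
#' mean of its neighbourhood, weights decaying with both spatial distance
#' and intensity difference, so edges (nucleus boundaries) are preserved.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param sigma_color Range kernel width as a fraction of the value range.
#' @param sigma_spatial Domain kernel width in pixels.
#' @param radius Neighbourhood radius; defaults to `2 * sigma_spatial`.
#' @return Filtered matrix, same dimensions.
#' @export
bilateral_smooth <- function(image, sigma_color = 0.05, sigma_spatial = 3,
                             radius = ceiling(2 * sigma_spatial)) {
  h <- nrow(image); w <- ncol(image)
  r <- as.integer(radius)
  # symmetric padding, then shift-and-accumulate over the window offsets
  rows <- reflect_index((-r):(h - 1L + r), h) + 1L
  cols <- reflect_index((-r):(w - 1L + r), w) + 1L
  pad <- image[rows, cols, drop = FALSE]
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (dy in (-r):r) {
    for (dx in (-r):r) {
      ws <- exp(-(dx^2 + dy^2) / (2 * sigma_spatial^2))
      shifted <- pad[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx),
                     drop = FALSE]
      wgt <- ws * exp(-(shifted - image)^2 / (2 * sigma_color^2))
      num <- num + wgt * shifted
      den <- den + wgt
    }
  }
  num / den
}
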