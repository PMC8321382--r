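#' Appearance parameters of the synthetic generator
#'
#' Nuclei are rendered as soft-edged ellipses whose size, darkness and
#' chromatin texture grow monotonically with a class-severity index
#' (NILM = 0 smallest/palest/smoothest ... SCC = 5 largest/darkest/most
#' textured), echoing the cytomorphology that grading relies on. Units:
#' radii in pixels, intensities in the \[0,1\] gray range.
#'
#' @return Named list: `radius_base`, `radius_step`, `radius_sd`,
#'   `intensity_base`, `intensity_step`, `texture_base`, `texture_step`.
#' @export
synth_params <- function() {
  list(radius_base = 7, radius_step = 3, radius_sd = 1,
       intensity_base = 0.38, intensity_step = -0.04,
       texture_base = 0.02, texture_step = 0.025)
}

#' Generate a synthetic cervical-cytology dataset
#'
#' Produces field images containing marked nuclei with class-dependent
#' appearance, plus the matching marks table, so the entire pipeline can
#' run without any external image collection. Nuclei are placed on a
#' jittered grid with centers at least `m` pixels apart, so every m-by-m
#' crop contains exactly one nucleus centroid. Fully deterministic under
#' `seed`.
#'
#' @param profile Named integer vector of requested marks per Bethesda
#'   label (e.g. [cric_counts()]); zero counts allowed.
#' @param image_size `c(height, width)` of the field images. The default
#'   255 x 344 is a quarter-scale field.
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, PNG images and
#'   `marks.csv` are written there.
#' @param m Crop size the placement must respect. Default 90.
#' @param params Appearance parameters, see [synth_params()].
#' @return A [cyto_dataset()] with the rendered images attached in memory.
#' @examples
#' ds <- generate_synthetic(c(NILM = 4, "ASC-US" = 0, LSIL = 0,
#'                            "ASC-H" = 0, HSIL = 4, SCC = 0), seed = 7)
#' dataset_counts(ds)
#' @export
generate_synthetic <- function(profile, image_size = c(255, 344), seed = 1L,
                               dir = NULL, m = 90, params = synth_params()) {
  labels6 <- bethesda_labels()
  if (is.null(names(profile)) || !all(names(profile) %in% labels6))
    stop("profile must be named by Bethesda labels")
  profile <- profile[profile > 0]
  h <- image_size[1]; w <- image_size[2]
  margin <- ceiling(m / 2) + 8
  spacing <- m + 12
  if (w < 2 * margin || h < 2 * margin)
    stop("image_size ", h, " x ", w, " cannot host any nucleus with m = ", m,
         "; use a larger image")
  xs <- seq(margin, w - margin, by = spacing)
  ys <- seq(margin, h - margin, by = spacing)
  slots <- expand.grid(x = xs, y = ys)
  total <- sum(profile)

  if (total == 0) {
    ds <- cyto_dataset(data.frame(image_id = character(0), x = integer(0),
                                  y = integer(0), label = character(0)),
                       images = list())
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_marks(ds, file.path(dir, "marks.csv"))
    }
    return(ds)
  }

  n_img <- ceiling(total / nrow(slots))
  severity <- stats::setNames(0:5, labels6)

  res <- with_seed(seed, {
    lab_seq <- sample(rep(names(profile), profile))
    images <- vector("list", n_img)
    names(images) <- sprintf("synth_%04d", seq_len(n_img))
    marks <- vector("list", n_img)
    k <- 0L
    for (ii in seq_len(n_img)) {
      img <- render_background(h, w)
      rows <- NULL
      for (si in seq_len(nrow(slots))) {
        if (k >= total) break
        k <- k + 1L
        lab <- lab_seq[k]
        s <- severity[[lab]]
        cx <- slots$x[si] + sample(-4:4, 1)
        cy <- slots$y[si] + sample(-4:4, 1)
        r <- max(3, stats::rnorm(1, params$radius_base + params$radius_step * s,
                                 params$radius_sd))
        img <- render_nucleus(img, cx, cy, r,
                              intensity = params$intensity_base +
                                params$intensity_step * s,
                              texture = params$texture_base +
                                params$texture_step * s)
        rows <- rbind(rows, data.frame(image_id = names(images)[ii],
                                       x = cx, y = cy, label = lab,
                                       stringsAsFactors = FALSE))
      }
      img <- clip01(img + matrix(stats::rnorm(h * w, 0, 0.015), h, w))
      images[[ii]] <- img
      marks[[ii]] <- rows
    }
    list(images = images[seq_len(ii)], marks = do.call(rbind, marks))
  })

  ds <- cyto_dataset(res$marks, images = res$images)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(res$images))
      write_raster(res$images[[id]], file.path(dir, paste0(id, ".png")))
    write_marks(ds, file.path(dir, "marks.csv"))
  }
  ds
}

# Cytoplasm-like background: pale base with a smooth low-frequency field.
render_background <- function(h, w) {
  coarse <- matrix(stats::rnorm(64, 0, 1), 8, 8)
  field <- resize_bilinear(coarse, h, w)
  clip01(0.78 + 0.05 * field)
}

# Draw one nucleus (plus a faint cytoplasm halo) into the image, editing
# only a local window around the center for speed.
render_nucleus <- function(img, cx, cy, r, intensity, texture) {
  h <- nrow(img); w <- ncol(img)
  ratio <- stats::runif(1, 0.8, 1.25)
  theta <- stats::runif(1, 0, pi)
  a <- r * ratio; b <- r / ratio
  halo <- 2.1 * max(a, b)
  x0 <- max(1, floor(cx + 1 - halo)); x1 <- min(w, ceiling(cx + 1 + halo))
  y0 <- max(1, floor(cy + 1 - halo)); y1 <- min(h, ceiling(cy + 1 + halo))
  dx <- outer(rep(1, y1 - y0 + 1), (x0:x1) - (cx + 1))
  dy <- outer((y0:y1) - (cy + 1), rep(1, x1 - x0 + 1))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  d_nuc <- sqrt((u / a)^2 + (v / b)^2)
  d_halo <- sqrt((u / (2 * a))^2 + (v / (2 * b))^2)
  win <- img[y0:y1, x0:x1]
  # cytoplasm halo: slightly darker, very soft edge
  win <- win - 0.10 * clip01((1.1 - d_halo) / 0.35)
  # nucleus body: dark ellipse with a soft rim
  body <- clip01((1.04 - d_nuc) / 0.12)
  chroma <- texture * (sin(u * stats::runif(1, 0.5, 0.9) +
                             stats::runif(1, 0, 2 * pi)) *
                       sin(v * stats::runif(1, 0.5, 0.9) +
                             stats::runif(1, 0, 2 * pi))) +
    matrix(stats::rnorm(length(win), 0, texture * 0.7), nrow(win))
  win <- win * (1 - body) + body * clip01(intensity + chroma)
  img[y0:y1, x0:x1] <- clip01(win)
  img
}
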