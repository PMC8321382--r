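#' Construct a marks dataset
#'
#' A `cyto_dataset` bundles a marks table (one row per annotated nucleus)
#' with an image store. Rows are kept in canonical order -- lexicographic by
#' (`image_id`, `mark_id`) -- so that "the first N images of a class" is a
#' reproducible notion regardless of input row order.
#'
#' @param marks data.frame with columns `image_id`, `x`, `y`, `label` and
#'   optionally `mark_id`, `source_mark`, `transform_tag`. Coordinates are
#'   0-based pixel indices, `x` the column and `y` the row. When `mark_id`
#'   is absent a stable key `"<image_id>@<x>_<y>"` is derived, so the key
#'   does not depend on row order.
#' @param images Named list mapping `image_id` to a numeric matrix in
#'   \[0,1\] (grayscale raster), or `NULL` when images live on disk.
#' @param image_dir Directory holding `<image_id>.png` (or `.tif`) files,
#'   or `NULL`.
#' @param image_size Optional `c(height, width)` used for mark bounds
#'   checking when no raster is attached.
#' @return An object of class `cyto_dataset`.
#' @export
cyto_dataset <- function(marks, images = NULL, image_dir = NULL,
                         image_size = NULL) {
  need <- c("image_id", "x", "y", "label")
  miss <- setdiff(need, names(marks))
  if (length(miss) > 0)
    stop("marks table is missing column(s): ", paste(miss, collapse = ", "))
  marks$image_id <- as.character(marks$image_id)
  marks$x <- as.integer(marks$x)
  marks$y <- as.integer(marks$y)
  marks$label <- as.character(marks$label)

  bad <- !(marks$label %in% bethesda_labels())
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("row %d: unknown label '%s' (expected one of %s)",
                 i, marks$label[i], paste(bethesda_labels(), collapse = ", ")))
  }
  if (is.null(marks$mark_id))
    marks$mark_id <- sprintf("%s@%d_%d", marks$image_id, marks$x, marks$y)
  marks$mark_id <- as.character(marks$mark_id)
  dup <- duplicated(marks$mark_id)
  if (any(dup))
    stop("duplicate mark_id: ", marks$mark_id[which(dup)[1]])
  if (is.null(marks$transform_tag))
    marks$transform_tag <- rep("identity", nrow(marks))
  if (is.null(marks$source_mark)) marks$source_mark <- marks$mark_id

  ord <- order(marks$image_id, marks$mark_id, method = "radix")
  marks <- marks[ord, , drop = FALSE]
  rownames(marks) <- NULL

  ds <- structure(list(marks = marks, images = images, image_dir = image_dir,
                       image_size = image_size),
                  class = "cyto_dataset")
  validate_bounds(ds)
  ds
}

# Bounds check: every mark must fall inside its image raster (when known).
validate_bounds <- function(ds) {
  m <- ds$marks
  if (nrow(m) == 0) return(invisible(ds))
  for (i in seq_len(nrow(m))) {
    sz <- NULL
    if (!is.null(ds$images) && !is.null(ds$images[[m$image_id[i]]]))
      sz <- dim(ds$images[[m$image_id[i]]])[1:2]
    else if (!is.null(ds$image_size))
      sz <- ds$image_size
    if (is.null(sz)) next
    if (m$x[i] < 0 || m$y[i] < 0 || m$x[i] >= sz[2] || m$y[i] >= sz[1])
      stop(sprintf("row %d: mark %s at (x=%d, y=%d) is outside image '%s' (%d x %d)",
                   i, m$mark_id[i], m$x[i], m$y[i], m$image_id[i], sz[1], sz[2]))
  }
  invisible(ds)
}

#' Per-class mark counts of a dataset
#'
#' @param dataset A [cyto_dataset()].
#' @param scheme Optional [class_scheme()]; when given, counts are over the
#'   scheme's target classes, otherwise over the six Bethesda labels.
#' @return Named integer vector, in label/target display order.
#' @export
dataset_counts <- function(dataset, scheme = NULL) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  if (is.null(scheme)) {
    lv <- bethesda_labels()
    lab <- dataset$marks$label
  } else {
    lv <- scheme$target_order
    lab <- map_label(scheme, dataset$marks$label)
  }
  tab <- table(factor(lab, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Retrieve a raster from a dataset's image store
#'
#' @param dataset A [cyto_dataset()].
#' @param image_id Image identifier.
#' @return Numeric matrix in \[0,1\].
#' @export
get_image <- function(dataset, image_id) {
  if (!is.null(dataset$images) && !is.null(dataset$images[[image_id]]))
    return(dataset$images[[image_id]])
  if (!is.null(dataset$image_dir)) {
    for (ext in c(".png", ".tif", ".tiff")) {
      p <- file.path(dataset$image_dir, paste0(image_id, ext))
      if (file.exists(p)) return(read_raster(p))
    }
  }
  stop("image '", image_id, "' not found in the dataset's image store")
}

# Subset a dataset by row indices into the canonical marks table,
# preserving canonical order.
dataset_subset <- function(dataset, idx) {
  m <- dataset$marks[sort(idx), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(marks = m, images = dataset$images,
                 image_dir = dataset$image_dir, image_size = dataset$image_size),
            class = "cyto_dataset")
}

#' @export
print.cyto_dataset <- function(x, ...) {
  cat("<cyto_dataset>", nrow(x$marks), "marks,",
      length(unique(x$marks$image_id)), "images\n")
  cnt <- dataset_counts(x)
  cat("  ", paste(sprintf("%s:%d", names(cnt), cnt), collapse = "  "), "\n")
  if (any(x$marks$transform_tag != "identity"))
    cat("  augmented samples:", sum(x$marks$transform_tag != "identity"), "\n")
  invisible(x)
}
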