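#' Read a marks table
#'
#' The marks CSV has a header `image_id,x,y,label` (comma-separated,
#' UTF-8). Coordinates are 0-based pixel indices with `x` the column and
#' `y` the row; `label` is one of the six Bethesda names. Rows are returned
#' in canonical (`image_id`, `mark_id`) order, so shuffling the file does
#' not change downstream behaviour.
#'
#' @param path Path to the marks CSV.
#' @param image_dir,images,image_size Passed to [cyto_dataset()]; used for
#'   image access and mark bounds checking.
#' @return A [cyto_dataset()].
#' @export
read_marks <- function(path, image_dir = NULL, images = NULL,
                       image_size = NULL) {
  if (!file.exists(path)) stop("marks file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  need <- c("image_id", "x", "y", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("marks file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  cyto_dataset(df[, need, drop = FALSE], images = images,
               image_dir = image_dir, image_size = image_size)
}

#' Write a marks table
#'
#' Inverse of [read_marks()]: emits the canonical `image_id,x,y,label` CSV
#' in canonical row order.
#'
#' @param dataset A [cyto_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marks <- function(dataset, path) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  utils::write.csv(dataset$marks[, c("image_id", "x", "y", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a split manifest
#'
#' Persists which split each mark belongs to, as a CSV with columns
#' `mark_id,split,scheme_label`. Reading it back with [read_manifest()]
#' reproduces the assignments exactly, in the same order.
#'
#' @param dataset A [cyto_dataset()].
#' @param assignments Named character vector `mark_id -> split`, with
#'   splits in `train`, `validation`, `test`. Every mark must be assigned.
#' @param path Output file path.
#' @param scheme Optional [class_scheme()] used to record each mark's
#'   target class; defaults to the six-class identity.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, assignments, path, scheme = NULL) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  ids <- dataset$marks$mark_id
  miss <- setdiff(ids, names(assignments))
  if (length(miss) > 0)
    stop("missing split assignment for mark(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  spl <- unname(assignments[ids])
  bad <- !(spl %in% c("train", "validation", "test"))
  if (length(spl) > 0 && any(bad))
    stop("invalid split value(s): ", paste(unique(spl[bad]), collapse = ", "))
  sl <- if (is.null(scheme)) dataset$marks$label
        else map_label(scheme, dataset$marks$label)
  df <- data.frame(mark_id = ids, split = spl, scheme_label = sl,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path Manifest CSV written by [write_manifest()].
#' @return data.frame with columns `mark_id`, `split`, `scheme_label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("mark_id", "split", "scheme_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  dup <- duplicated(df$mark_id)
  if (any(dup))
    stop("manifest contains duplicate mark_id: ", df$mark_id[which(dup)[1]])
  bad <- !(df$split %in% c("train", "validation", "test")) & nrow(df) > 0
  if (any(bad))
    stop("manifest contains invalid split value(s): ",
         paste(unique(df$split[bad]), collapse = ", "))
  df
}

#' Read a raster image as a grayscale matrix
#'
#' PNG and TIF are supported. Multi-channel images are reduced to
#' grayscale by averaging the first three channels.
#'
#' @param path Image file path.
#' @return Numeric matrix with values in \[0,1\]; rows are image rows.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3)
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  img
}

#' Write a grayscale matrix as a PNG
#'
#' @param image Numeric matrix in \[0,1\].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}
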