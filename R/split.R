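#' Stratified holdout split of the test set
#'
#' Per six-class label with `n` marks, the test set receives
#' `ceiling(test_fraction * n)` marks drawn uniformly at random under
#' `seed`; the remainder forms the train/validation pool. The ceiling rule
#' is what reproduces the published per-class test sizes (e.g. 175 of 874
#' HSIL marks at 20%). Counts are a deterministic function of the class
#' sizes; the seed only decides membership.
#'
#' @param dataset A [cyto_dataset()] of original (unaugmented) marks.
#' @param test_fraction Fraction held out per class, in (0,1). Default 0.2.
#' @param seed Integer seed.
#' @param labels Classes the split must cover; a class in `labels` with
#'   zero marks is an error. Defaults to all six Bethesda labels; pass a
#'   subset for deliberately partial datasets.
#' @return List with elements `pool` and `test`, both [cyto_dataset()]s.
#' @export
split_test <- function(dataset, test_fraction = 0.2, seed = 1L,
                       labels = bethesda_labels()) {
  stopifnot(inherits(dataset, "cyto_dataset"),
            test_fraction > 0, test_fraction < 1)
  lab <- dataset$marks$label
  present <- unique(lab)
  empty <- setdiff(labels, present)
  if (length(empty) > 0)
    stop("cannot split: class(es) with zero marks: ",
         paste(empty, collapse = ", "))
  idx_test <- stratified_holdout(lab, test_fraction, seed)
  list(pool = dataset_subset(dataset, setdiff(seq_along(lab), idx_test)),
       test = dataset_subset(dataset, idx_test))
}

#' Stratified re-split of the validation set
#'
#' Applied to the balanced pool: per six-class label with `p` samples,
#' validation receives `ceiling(val_fraction * p)` samples. Stratifying by
#' the six Bethesda labels (rather than any coarser target grouping)
#' reproduces the published per-class validation sizes under every scheme
#' -- e.g. 135 of the 671 balanced SCC samples -- and fixes the grouped
#' counts as sums of per-class ceilings. Because balancing precedes this
#' split, augmented copies of one source image may land on both sides;
#' pass `group_by_source = TRUE` to keep every sample derived from one
#' source mark on a single side (the per-class ceiling counts then hold
#' for source marks, not samples).
#'
#' @param pool A [cyto_dataset()], typically the balanced pool.
#' @param val_fraction Fraction per class, in (0,1). Default 0.2.
#' @param seed Integer seed.
#' @param group_by_source Keep all augmented copies of a source mark on one
#'   side. Default `FALSE`, matching the published counts.
#' @return List with elements `train` and `validation`.
#' @export
split_validation <- function(pool, val_fraction = 0.2, seed = 1L,
                             group_by_source = FALSE) {
  stopifnot(inherits(pool, "cyto_dataset"),
            val_fraction > 0, val_fraction < 1)
  lab <- pool$marks$label
  if (group_by_source) {
    src <- pool$marks$source_mark
    groups <- !duplicated(src)
    gidx <- stratified_holdout(lab[groups], val_fraction, seed)
    val_src <- src[groups][gidx]
    idx_val <- which(src %in% val_src)
  } else {
    idx_val <- stratified_holdout(lab, val_fraction, seed)
  }
  list(train = dataset_subset(pool, setdiff(seq_along(lab), idx_val)),
       validation = dataset_subset(pool, idx_val))
}

# Indices of the held-out side: per stratum of `lab`, ceiling(frac * n)
# elements sampled without replacement under `seed`.
stratified_holdout <- function(lab, frac, seed) {
  out <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(lab))) {
      idx <- which(lab == cl)
      k <- ceiling(frac * length(idx))
      pick <- if (length(idx) == 1L) rep(idx, k) else sample(idx, k)
      out <- c(out, pick)
    }
  })
  sort(out)
}
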