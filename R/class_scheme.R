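#' Bethesda System labels used throughout the package
#'
#' The six cytology classes, in severity order: NILM (normal), ASC-US, LSIL,
#' ASC-H, HSIL, SCC. This ordering fixes confusion-matrix axes and the
#' severity index used by the synthetic generator.
#'
#' @return Character vector of the six label names.
#' @export
bethesda_labels <- function() {
  c("NILM", "ASC-US", "LSIL", "ASC-H", "HSIL", "SCC")
}

#' Define a 2-, 3- or 6-way class grouping scheme
#'
#' Cervical cytology labels are grouped in three clinically motivated ways:
#' `"two"` separates normal (NILM) from altered cells (all five lesion
#' classes); `"three"` separates normal, low-grade lesions (ASC-US, LSIL)
#' and high-grade lesions (ASC-H, HSIL, SCC), mirroring the follow-up
#' pathways (repeat in 3 years / repeat in 6-12 months / colposcopy);
#' `"six"` keeps the Bethesda labels as-is.
#'
#' @param name One of `"two"`, `"three"`, `"six"` (also accepts 2, 3, 6).
#' @return An object of class `class_scheme` with elements `name`,
#'   `mapping` (named character: six-label -> target class) and
#'   `target_order` (display order of target classes).
#' @examples
#' sch <- class_scheme("three")
#' map_label(sch, "HSIL")
#' @export
class_scheme <- function(name = c("six", "three", "two")) {
  if (is.numeric(name)) name <- c("2" = "two", "3" = "three", "6" = "six")[as.character(name)]
  name <- match.arg(as.character(name), c("six", "three", "two"))
  six <- bethesda_labels()
  mapping <- switch(name,
    two = c("NILM" = "normal", "ASC-US" = "altered", "LSIL" = "altered",
            "ASC-H" = "altered", "HSIL" = "altered", "SCC" = "altered"),
    three = c("NILM" = "normal", "ASC-US" = "low-grade", "LSIL" = "low-grade",
              "ASC-H" = "high-grade", "HSIL" = "high-grade", "SCC" = "high-grade"),
    six = stats::setNames(six, six)
  )
  target_order <- switch(name,
    two = c("normal", "altered"),
    three = c("normal", "low-grade", "high-grade"),
    six = six
  )
  structure(list(name = name, mapping = mapping, target_order = target_order),
            class = "class_scheme")
}

#' Map Bethesda labels onto a scheme's target classes
#'
#' @param scheme A [class_scheme()].
#' @param label Character vector of six-class labels.
#' @return Character vector of target class names (same length as `label`).
#' @export
map_label <- function(scheme, label) {
  stopifnot(inherits(scheme, "class_scheme"))
  bad <- setdiff(unique(label), names(scheme$mapping))
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(bethesda_labels(), collapse = ", "))
  unname(scheme$mapping[label])
}

#' Six-class members of each target class
#'
#' @param scheme A [class_scheme()].
#' @return Named list: target class name -> character vector of Bethesda
#'   labels mapped to it, in severity order.
#' @export
scheme_groups <- function(scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  lapply(stats::setNames(scheme$target_order, scheme$target_order),
         function(tc) names(scheme$mapping)[scheme$mapping == tc])
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme>", x$name, "\n")
  for (tc in x$target_order)
    cat(sprintf("  %-10s <- %s\n", tc,
                paste(names(x$mapping)[x$mapping == tc], collapse = ", ")))
  invisible(x)
}
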