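#' Pool class counts of the reference cervical-cytology collection
#'
#' Per-class train/validation pool sizes left after the 20% test holdout of
#' the 862/286/598/536/874/77 collection; the hand-made literal balancing
#' plans are defined for exactly these counts.
#'
#' @return Named integer vector over the six Bethesda labels.
#' @export
cric_pool_counts <- function() {
  c("NILM" = 689L, "ASC-US" = 228L, "LSIL" = 478L,
    "ASC-H" = 428L, "HSIL" = 699L, "SCC" = 61L)
}

#' Full class counts of the reference cervical-cytology collection
#'
#' @return Named integer vector over the six Bethesda labels (total 3233).
#' @export
cric_counts <- function() {
  c("NILM" = 862L, "ASC-US" = 286L, "LSIL" = 598L,
    "ASC-H" = 536L, "HSIL" = 874L, "SCC" = 77L)
}

#' Plan the augmentation schedule that balances class sizes
#'
#' Builds a per-class schedule of (source subset size, transforms each)
#' whose expansion equalizes class -- or class-group -- sizes.
#'
#' In `"general"` mode the reference target `T` is the largest six-class
#' count inside the largest group (the group with the most Bethesda
#' members; ties go to the larger pool). Each group is sized to
#' `k_max * T` samples, split as evenly as possible over its member
#' classes; a class with `n` sources and deficit `e = target - n` assigns
#' `q + 1 = floor(e/n) + 1` transforms to `e mod n` randomly chosen
#' sources and `q` to the rest, reaching its target exactly. Classes
#' already at or above target are left untouched (sources are never
#' dropped).
#'
#' `"paper"` mode reproduces the published hand-made schedules verbatim
#' (including their off-by-one quirks, e.g. ASC-H stopping at 698 rather
#' than 699) and is only valid for the reference pool counts of
#' [cric_pool_counts()].
#'
#' @param pool_counts Named integer vector of post-test-split counts over
#'   the six Bethesda labels.
#' @param scheme A [class_scheme()].
#' @param mode `"general"` or `"paper"`.
#' @return An object of class `aug_plan`: data.frame `entries` with columns
#'   `class`, `subset_size`, `transforms_each`, `selection`
#'   (`first`/`random`/`rest`/`all`), plus attributes `target_sizes`
#'   (planned per-class sizes), `scheme`, `mode`.
#' @examples
#' plan_balance(cric_pool_counts(), class_scheme("six"), mode = "paper")
#' @export
plan_balance <- function(pool_counts, scheme, mode = c("general", "paper")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "class_scheme"))
  six <- bethesda_labels()
  if (!all(six %in% names(pool_counts)))
    stop("pool_counts must be named over all six Bethesda labels")
  n <- as.integer(pool_counts[six])
  names(n) <- six
  if (any(n < 0)) stop("negative pool counts")

  if (mode == "paper") {
    ref <- cric_pool_counts()
    if (!all(n == ref))
      stop("paper mode is only valid for the reference pool counts (",
           paste(ref, collapse = ", "), "); got (",
           paste(n, collapse = ", "), ")")
    entries <- paper_plan_entries(scheme$name)
  } else {
    entries <- general_plan_entries(n, scheme)
  }

  sizes <- vapply(six, function(cl) {
    e <- entries[entries$class == cl, , drop = FALSE]
    n[[cl]] + sum(e$subset_size * e$transforms_each)
  }, integer(1))

  structure(list(entries = entries, pool_counts = n,
                 target_sizes = sizes, scheme = scheme$name, mode = mode),
            class = "aug_plan")
}

# The published hand-made schedules, per scheme.
paper_plan_entries <- function(scheme_name) {
  row <- function(class, subset, each, sel)
    data.frame(class = class, subset_size = as.integer(subset),
               transforms_each = as.integer(each), selection = sel,
               stringsAsFactors = FALSE)
  six_altered <- rbind(
    row("ASC-US", 228, 2, "all"),      # 228 -> 684
    row("LSIL", 220, 1, "random"),     # 478 -> 698
    row("ASC-H", 270, 1, "random"),    # 428 -> 698
    row("SCC", 61, 10, "all")          # 61  -> 671
  )
  switch(scheme_name,
    six = six_altered,
    three = rbind(
      row("NILM", 689, 2, "all"),      # 689 -> 2067
      row("ASC-US", 130, 4, "first"),  # 228 -> 1042
      row("ASC-US", 98, 3, "rest"),
      row("LSIL", 100, 2, "first"),    # 478 -> 1056
      row("LSIL", 378, 1, "rest"),
      row("ASC-H", 270, 1, "random"),
      row("SCC", 61, 10, "all")
    ),
    two = rbind(
      row("NILM", 689, 4, "all"),      # 689 -> 3445
      six_altered
    )
  )
}

# Clean integer schedule: equal-split group targets, q/r remainder rule.
general_plan_entries <- function(n, scheme) {
  groups <- scheme_groups(scheme)
  k <- lengths(groups)
  pool_by_group <- vapply(groups, function(g) sum(n[g]), integer(1))
  # largest group by member count; pool size breaks ties
  gi <- order(-k, -pool_by_group)[1]
  ref_group <- groups[[gi]]
  target_ref <- max(n[ref_group])
  entries <- NULL
  for (g in names(groups)) {
    members <- groups[[g]]
    kg <- length(members)
    total <- length(ref_group) * target_ref
    base <- total %/% kg
    extra <- total %% kg
    targets <- base + as.integer(seq_len(kg) <= extra)
    for (j in seq_len(kg)) {
      cl <- members[j]
      e <- targets[j] - n[[cl]]
      if (e <= 0 || n[[cl]] == 0) next
      q <- e %/% n[[cl]]
      r <- e %% n[[cl]]
      rows <- NULL
      if (r > 0)
        rows <- data.frame(class = cl, subset_size = r,
                           transforms_each = q + 1L, selection = "random",
                           stringsAsFactors = FALSE)
      if (n[[cl]] - r > 0 && q > 0)
        rows <- rbind(rows, data.frame(class = cl, subset_size = n[[cl]] - r,
                                       transforms_each = q,
                                       selection = if (r > 0) "rest" else "all",
                                       stringsAsFactors = FALSE))
      entries <- rbind(entries, rows)
    }
  }
  if (is.null(entries))
    entries <- data.frame(class = character(0), subset_size = integer(0),
                          transforms_each = integer(0),
                          selection = character(0), stringsAsFactors = FALSE)
  entries
}

#' Planned per-class sizes of an augmentation plan
#'
#' @param plan An [plan_balance()] result.
#' @return Named integer vector over the six Bethesda labels: pool count
#'   plus scheduled augmentations.
#' @export
planned_sizes <- function(plan) {
  stopifnot(inherits(plan, "aug_plan"))
  plan$target_sizes
}

#' @export
print.aug_plan <- function(x, ...) {
  cat(sprintf("<aug_plan> scheme=%s mode=%s\n", x$scheme, x$mode))
  print(x$entries, row.names = FALSE)
  cat("planned sizes:",
      paste(sprintf("%s:%d", names(x$target_sizes), x$target_sizes),
            collapse = "  "), "\n")
  invisible(x)
}

#' Serialize an augmentation plan to JSON
#'
#' @param plan An `aug_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(scheme = plan$scheme, mode = plan$mode,
         pool_counts = as.list(plan$pool_counts),
         target_sizes = as.list(plan$target_sizes),
         entries = plan$entries),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Expand a pool dataset according to an augmentation plan
#'
#' Realizes the plan: every original sample is kept, and each scheduled
#' source mark receives its number of transforms, drawn without
#' replacement from the 10 tags under `seed` so no source ever repeats a
#' tag. `"first"`/`"rest"` subsets use canonical dataset order;
#' `"random"` subsets are seeded draws.
#'
#' @param pool A [cyto_dataset()] of original marks.
#' @param plan An [plan_balance()] result valid for this pool.
#' @param seed Integer seed.
#' @return A [cyto_dataset()] whose per-class sizes equal
#'   [planned_sizes()]; augmented rows carry `source_mark` and
#'   `transform_tag` provenance and `mark_id = "<source>#<tag>"`.
#' @export
expand_pool <- function(pool, plan, seed = 1L) {
  stopifnot(inherits(pool, "cyto_dataset"), inherits(plan, "aug_plan"))
  cnt <- dataset_counts(pool)
  if (!all(cnt == plan$pool_counts))
    stop("plan was built for pool counts (",
         paste(plan$pool_counts, collapse = ", "),
         ") but the pool has (", paste(cnt, collapse = ", "), ")")
  marks <- pool$marks
  aug_rows <- list()
  for (cl in unique(plan$entries$class)) {
    cls_idx <- which(marks$label == cl)        # canonical order
    ent <- plan$entries[plan$entries$class == cl, , drop = FALSE]
    taken <- integer(0)
    n_transforms <- integer(length(cls_idx))
    for (j in seq_len(nrow(ent))) {
      sel <- ent$selection[j]
      size <- ent$subset_size[j]
      avail <- setdiff(seq_along(cls_idx), taken)
      pick <- switch(sel,
        all = seq_along(cls_idx),
        first = seq_len(size),
        rest = avail[seq_len(size)],
        random = with_seed(sub_seed(seed, match(cl, bethesda_labels()) * 7 + j),
                           sort(sample(avail, size))),
        stop("unknown selection: ", sel))
      if (length(pick) != size)
        stop("plan entry for ", cl, " requests ", size,
             " sources but only ", length(pick), " are available")
      taken <- union(taken, pick)
      n_transforms[pick] <- n_transforms[pick] + ent$transforms_each[j]
    }
    if (any(n_transforms > 10))
      warning("class ", cl, ": more than 10 transforms per source; ",
              "tags will be reused")
    for (k in which(n_transforms > 0)) {
      i <- cls_idx[k]
      tags <- draw_tags(n_transforms[k], sub_seed(seed, i * 13 + 1))
      rows <- marks[rep(i, length(tags)), , drop = FALSE]
      rows$mark_id <- make.unique(paste0(marks$mark_id[i], "#", tags),
                                  sep = "~")
      rows$source_mark <- marks$mark_id[i]
      rows$transform_tag <- tags
      aug_rows[[length(aug_rows) + 1]] <- rows
    }
  }
  all_marks <- rbind(marks, do.call(rbind, aug_rows))
  cyto_dataset(all_marks, images = pool$images, image_dir = pool$image_dir,
               image_size = pool$image_size)
}

# Draw k transform tags without replacement; if k > 10 the deck is
# reshuffled and reused (never occurs at the reference scale).
draw_tags <- function(k, seed) {
  tags <- character(0)
  d <- 0L
  while (length(tags) < k) {
    tags <- c(tags, with_seed(sub_seed(seed, d), sample(aug_tags())))
    d <- d + 1L
  }
  tags[seq_len(k)]
}
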