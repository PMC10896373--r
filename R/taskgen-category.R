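#' Feature space for category-learning tasks
#'
#' The stimulus universe from which category tasks are sampled: a pool of
#' discrete feature dimensions (e.g. line length, orientation, ...), each
#' taking `values_per_dim` ordered values. Every sampled task uses two
#' dimensions drawn from the pool, giving `values_per_dim^2` items.
#'
#' @param pool_size number of distinct feature dimensions available to the
#'   metalearning distribution (default 200).
#' @param values_per_dim number of ordered values per dimension (default 8).
#' @return an object of class `feature_space`.
#' @export
feature_space <- function(pool_size = 200L, values_per_dim = 8L) {
  pool_size <- as.integer(pool_size)
  values_per_dim <- as.integer(values_per_dim)
  if (is.na(pool_size) || pool_size < 2L)
    stop("invalid feature space: pool_size must be >= 2")
  if (is.na(values_per_dim) || values_per_dim < 2L)
    stop("invalid feature space: values_per_dim must be >= 2")
  structure(list(pool_size = pool_size, values_per_dim = values_per_dim),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d dimensions x %d values\n",
              x$pool_size, x$values_per_dim))
  invisible(x)
}

category_conditions <- c("rule_like", "rotated")

#' Sample a category-learning task
#'
#' Draws two distinct feature dimensions from the pool, assigns every item
#' (value pair) to one of two categories via a balanced boundary, randomly
#' maps the categories to the label tokens 'A'/'B', and selects 16 study
#' items per category; the remaining 32 items are held out.
#'
#' In the `rule_like` condition one randomly chosen dimension determines
#' membership (value <= midpoint vs above, e.g. 'A' if length <= 4).  In the
#' `rotated` condition membership depends on the anti-diagonal coordinate
#' (the sum of both values); items on the central diagonal are split
#' deterministically by parity of the first value so that the 64 items
#' always divide 32/32.
#'
#' @param space a [feature_space()].
#' @param condition `"rule_like"` or `"rotated"`.
#' @param seed optional integer; when supplied the draw is a pure function
#'   of `(space, condition, seed)`.
#' @return an object of class `category_task` with fields `dims`,
#'   `condition`, `boundary`, `items` (data frame of `v1`, `v2`, `label`),
#'   `study` and `heldout` (row indices into `items`).
#' @export
sample_category_task <- function(space = feature_space(),
                                 condition = c("rule_like", "rotated"),
                                 seed = NULL) {
  condition <- match.arg(condition)
  if (!inherits(space, "feature_space")) space <- do.call(feature_space, space)
  sample_fn <- function() {
    dims <- sample.int(space$pool_size, 2L)
    nv <- space$values_per_dim
    boundary <- list(
      condition = condition,
      relevant_dim = if (condition == "rule_like") sample.int(2L, 1L) else NA_integer_,
      threshold = if (condition == "rule_like") nv %/% 2L else nv + 1L,
      tie_break = "parity_v1",
      # polarity 1: low side of the boundary is category 1; 2: flipped
      polarity = sample.int(2L, 1L)
    )
    # which category maps to label token 'A' vs 'B'
    label_map <- sample(c("A", "B"))
    grid <- expand.grid(v1 = seq_len(nv), v2 = seq_len(nv),
                        KEEP.OUT.ATTRS = FALSE)
    lab <- category_label(as.matrix(grid), boundary)
    items <- data.frame(v1 = grid$v1, v2 = grid$v2,
                        label = label_map[lab], stringsAsFactors = FALSE)
    study <- integer(0)
    for (lv in c("A", "B")) {
      idx <- which(items$label == lv)
      study <- c(study, sample(idx, length(idx) %/% 2L))
    }
    structure(list(dims = dims, condition = condition, boundary = boundary,
                   label_map = label_map, space = space, items = items,
                   study = sort(study),
                   heldout = setdiff(seq_len(nrow(items)), study)),
              class = "category_task")
  }
  if (is.null(seed)) sample_fn() else withr::with_seed(seed, sample_fn())
}

#' @export
print.category_task <- function(x, ...) {
  cat(sprintf("<category_task> %s, dims (%d, %d), %d items (%d study / %d held out)\n",
              x$condition, x$dims[1], x$dims[2], nrow(x$items),
              length(x$study), length(x$heldout)))
  invisible(x)
}

check_item_domain <- function(item, boundary) {
  nv <- boundary$values_per_dim %||% 8L
  if (any(item < 1L) || any(item != floor(item)))
    stop("item values outside the feature-value domain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label an item under a rule-like boundary
#'
#' Membership depends only on the relevant dimension: values up to the
#' threshold fall on the low side ('A' if length <= 4 under the default
#' polarity), the rest on the high side.
#'
#' @param item length-2 integer vector (or 2-column matrix) of feature values.
#' @param boundary the `boundary` component of a rule-like [sample_category_task()].
#' @return integer category index (1 = low side under polarity 1), one per item.
#' @export
rule_label <- function(item, boundary) {
  stopifnot(boundary$condition == "rule_like")
  item <- rbind(item)
  if (any(item < 1) || any(item != floor(item)))
    stop("item values outside the feature-value domain")
  low <- item[, boundary$relevant_dim] <= boundary$threshold
  cat1 <- if (boundary$polarity == 1L) low else !low
  as.integer(ifelse(unname(cat1), 1L, 2L))
}

#' Label an item under a 45-degree rotated boundary
#'
#' Membership depends on the anti-diagonal coordinate `v1 + v2` compared to
#' the central threshold; the items exactly on the boundary diagonal are
#' assigned by parity of `v1` (the `tie_break`), which splits them evenly.
#'
#' @inheritParams rule_label
#' @export
rotated_label <- function(item, boundary) {
  stopifnot(boundary$condition == "rotated")
  item <- rbind(item)
  if (any(item < 1) || any(item != floor(item)))
    stop("item values outside the feature-value domain")
  s <- item[, 1] + item[, 2]
  low <- s < boundary$threshold
  tie <- s == boundary$threshold
  if (any(tie)) {
    if (boundary$tie_break != "parity_v1")
      stop("unknown tie_break rule: ", boundary$tie_break)
    low[tie] <- item[tie, 1] %% 2L == 1L
  }
  cat1 <- if (boundary$polarity == 1L) low else !low
  as.integer(ifelse(unname(cat1), 1L, 2L))
}

category_label <- function(item, boundary) {
  if (boundary$condition == "rule_like") rule_label(item, boundary)
  else rotated_label(item, boundary)
}

#' Order the study items of a category task into a curriculum
#'
#' In the `blocked` condition the 16 items of one category are presented
#' first (which category leads is random), followed by the 16 of the other;
#' order within a block is shuffled. In the `interleaved` condition all 32
#' study items are uniformly shuffled.
#'
#' @param task a [sample_category_task()].
#' @param condition `"blocked"` or `"interleaved"`.
#' @param seed optional integer seed.
#' @return object of class `curriculum`: `order` (row indices into
#'   `task$items`, length 32), `condition`, `block_boundaries`.
#' @export
make_curriculum <- function(task, condition = c("blocked", "interleaved"),
                            seed = NULL) {
  condition <- match.arg(condition)
  fn <- function() {
    labels <- task$items$label[task$study]
    if (condition == "blocked") {
      first <- sample(c("A", "B"), 1L)
      ord <- c(sample(task$study[labels == first]),
               sample(task$study[labels != first]))
      bb <- length(task$study) %/% 2L
    } else {
      ord <- sample(task$study)
      bb <- integer(0)
    }
    structure(list(order = ord, condition = condition,
                   block_boundaries = bb), class = "curriculum")
  }
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

#' Serialize category tasks to JSON lines
#'
#' One task per line; [read_category_tasks_jsonl()] round-trips the result.
#'
#' @param tasks list of `category_task` objects.
#' @param path output file path.
#' @export
write_category_tasks_jsonl <- function(tasks, path) {
  lines <- vapply(tasks, function(t) {
    jsonlite::toJSON(list(
      family = "category", dims = t$dims, condition = t$condition,
      boundary = t$boundary, label_map = t$label_map,
      space = unclass(t$space), items = t$items,
      study = t$study), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_category_tasks_jsonl
#' @export
read_category_tasks_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    boundary <- as.list(x$boundary)
    rd <- boundary$relevant_dim
    boundary$relevant_dim <- if (is.null(rd) || is.na(suppressWarnings(
      as.integer(rd)))) NA_integer_ else as.integer(rd)
    structure(list(
      dims = as.integer(x$dims), condition = x$condition,
      boundary = boundary, label_map = x$label_map,
      space = feature_space(x$space$pool_size, x$space$values_per_dim),
      items = data.frame(v1 = as.integer(x$items$v1),
                         v2 = as.integer(x$items$v2),
                         label = x$items$label, stringsAsFactors = FALSE),
      study = as.integer(x$study),
      heldout = setdiff(seq_len(nrow(x$items)), as.integer(x$study))),
      class = "category_task")
  })
}
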