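#' @name grid_task
#' @title Compositional 5x5 grid tasks
#'
#' @description
#' Each task pairs 5 color words with 5 animal words on a 5x5 coordinate
#' grid. In the `rule_like` condition one feature determines the
#' x-coordinate and the other determines the y-coordinate (color = x and
#' animal = y, or vice versa), so locations can be predicted for unseen
#' color-animal combinations by composing the two per-feature mappings.
#' The `rotated` condition applies a 45-degree rotation with integer
#' rescaling, after which no single feature determines either coordinate.
NULL

grid_colors <- c("red", "blue", "green", "yellow", "purple")
grid_animals <- c("alligator", "bear", "cat", "dog", "elephant")

#' Sample a compositional grid task
#'
#' Shuffles the color and animal lists, assigns one feature to each axis,
#' and (for `rotated`) maps the grid through `(u, v) = (x - y + 4, x + y)`.
#' Coordinates are 0-based: 0..4 unrotated, 0..8 after rotation.
#'
#' @param condition `"rule_like"` or `"rotated"`.
#' @param seed optional integer seed.
#' @return object of class `grid_task`: `color_order`, `animal_order`,
#'   `axis_assignment` (`"color_x"` or `"animal_x"`), `rotated`, and
#'   `locations` (25-row data frame `color`, `animal`, `x`, `y`).
#' @export
sample_grid_task <- function(condition = c("rule_like", "rotated"),
                             seed = NULL) {
  condition <- match.arg(condition)
  fn <- function() {
    color_order <- sample(grid_colors)
    animal_order <- sample(grid_animals)
    axis_assignment <- sample(c("color_x", "animal_x"), 1L)
    grid <- expand.grid(ci = 0:4, ai = 0:4, KEEP.OUT.ATTRS = FALSE)
    if (axis_assignment == "color_x") {
      x <- grid$ci; y <- grid$ai
    } else {
      x <- grid$ai; y <- grid$ci
    }
    locations <- data.frame(color = color_order[grid$ci + 1L],
                            animal = animal_order[grid$ai + 1L],
                            x = x, y = y, stringsAsFactors = FALSE)
    if (condition == "rotated") locations <- rotate_grid(locations)
    structure(list(color_order = color_order, animal_order = animal_order,
                   axis_assignment = axis_assignment,
                   rotated = condition == "rotated",
                   condition = condition, locations = locations),
              class = "grid_task")
  }
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

#' @export
print.grid_task <- function(x, ...) {
  cat(sprintf("<grid_task> %s, %s, 25 cues\n", x$condition,
              x$axis_assignment))
  invisible(x)
}

#' Rotate a rule-like grid by 45 degrees with integer rescaling
#'
#' Applies `(u, v) = (x - y + 4, x + y)` to every cue location. This is a
#' 45-degree rotation scaled by `sqrt(2)` and shifted so all coordinates are
#' non-negative integers (0..8); it is injective on the 5x5 grid.
#'
#' @param locations data frame with columns `color`, `animal`, `x`, `y`
#'   where `x`, `y` are integers in 0..4.
#' @return the same data frame with transformed `x`, `y`.
#' @export
rotate_grid <- function(locations) {
  if (!all(c("color", "animal", "x", "y") %in% names(locations)))
    stop("locations must have columns color, animal, x, y")
  if (any(locations$x < 0 | locations$x > 4 |
          locations$y < 0 | locations$y > 4) ||
      any(locations$x != floor(locations$x)) ||
      any(locations$y != floor(locations$y)))
    stop("rotate_grid expects a 0-based 5x5 grid")
  u <- locations$x - locations$y + 4L
  v <- locations$x + locations$y
  locations$x <- as.integer(u)
  locations$y <- as.integer(v)
  locations
}

#' Invert [rotate_grid()]
#' @param locations data frame produced by [rotate_grid()].
#' @return the original 0..4 grid coordinates.
#' @export
unrotate_grid <- function(locations) {
  x <- (locations$x - 4L + locations$y) / 2
  y <- (locations$y - (locations$x - 4L)) / 2
  locations$x <- as.integer(x)
  locations$y <- as.integer(y)
  locations
}

#' Build the row-plus-column study curriculum for a grid task
#'
#' Chooses one grid row and one grid column uniformly; the 9 study cues are
#' the full row plus the full column (their intersection appears once, in
#' the first block). `blocked` presents one line in full before the other
#' (which comes first is random); `interleaved` shuffles the same 9 cues.
#' The remaining 16 cues form the generalization test set.
#'
#' @param task a [sample_grid_task()].
#' @param condition `"blocked"` or `"interleaved"`.
#' @param seed optional integer seed.
#' @return object of class `grid_curriculum`: `order` (9 row indices into
#'   `task$locations`), `test` (16 indices), `condition`, `block_order`,
#'   `groups` (per-presentation group id, `"row"`/`"col"`),
#'   `block_boundaries`.
#' @export
make_grid_curriculum <- function(task,
                                 condition = c("blocked", "interleaved"),
                                 seed = NULL) {
  condition <- match.arg(condition)
  fn <- function() {
    # "row" = the set of cues sharing one animal; "col" = sharing one color.
    row_animal <- sample(task$animal_order, 1L)
    col_color <- sample(task$color_order, 1L)
    loc <- task$locations
    row_idx <- which(loc$animal == row_animal)
    col_idx <- which(loc$color == col_color)
    inter <- intersect(row_idx, col_idx)
    block_order <- sample(c("row_first", "column_first"), 1L)
    if (block_order == "row_first") {
      first <- row_idx; second <- setdiff(col_idx, inter)
      groups <- c(rep("row", 5L), rep("col", 4L))
    } else {
      first <- col_idx; second <- setdiff(row_idx, inter)
      groups <- c(rep("col", 5L), rep("row", 4L))
    }
    ord <- c(sample(first), sample(second))
    bb <- 5L
    if (condition == "interleaved") {
      perm <- sample.int(9L)
      ord <- ord[perm]
      groups <- groups[perm]
      bb <- integer(0)
    }
    structure(list(order = ord, test = setdiff(seq_len(25L), union(row_idx, col_idx)),
                   condition = condition, block_order = block_order,
                   row_value = row_animal, column_value = col_color,
                   groups = groups, block_boundaries = bb),
              class = "grid_curriculum")
  }
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

#' Symbolic compositional oracle for rule-like grid tasks
#'
#' Infers, from the study examples alone, which coordinate each feature
#' determines, and composes the query's color-determined coordinate with its
#' animal-determined coordinate. Used as the independent reference against
#' which model generalization is validated.
#'
#' @param study data frame of study cues (columns `color`, `animal`, `x`, `y`).
#' @param color,animal the query cue's features (each must occur in `study`).
#' @return integer vector `c(x, y)`.
#' @export
compositional_answer <- function(study, color, animal) {
  if (!color %in% study$color || !animal %in% study$animal)
    stop("query features must each appear among the study cues")
  determines <- function(feature, coord) {
    tab <- unique(study[, c(feature, coord)])
    !any(duplicated(tab[[feature]]))
  }
  color_x <- determines("color", "x") && determines("animal", "y")
  animal_x <- determines("animal", "x") && determines("color", "y")
  if (color_x) {
    x <- study$x[match(color, study$color)]
    y <- study$y[match(animal, study$animal)]
  } else if (animal_x) {
    x <- study$x[match(animal, study$animal)]
    y <- study$y[match(color, study$color)]
  } else {
    stop("oracle not applicable: no per-feature coordinate rule fits the study set")
  }
  c(x = x, y = y)
}

#' Serialize grid tasks to JSON lines
#' @param tasks list of `grid_task` objects.
#' @param path output file path.
#' @export
write_grid_tasks_jsonl <- function(tasks, path) {
  lines <- vapply(tasks, function(t) {
    jsonlite::toJSON(list(
      family = "compositional", color_order = t$color_order,
      animal_order = t$animal_order, axis_assignment = t$axis_assignment,
      condition = t$condition, locations = t$locations), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid_tasks_jsonl
#' @export
read_grid_tasks_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    structure(list(color_order = x$color_order, animal_order = x$animal_order,
                   axis_assignment = x$axis_assignment,
                   rotated = x$condition == "rotated",
                   condition = x$condition,
                   locations = data.frame(color = x$locations$color,
                                          animal = x$locations$animal,
                                          x = as.integer(x$locations$x),
                                          y = as.integer(x$locations$y),
                                          stringsAsFactors = FALSE)),
              class = "grid_task")
  })
}

#' Human-readable rendering of a grid curriculum
#'
#' Prints one study example per line ("blue alligator -> (3, 2)") followed by
#' the query cues; useful for inspection and for prompt-style harnesses.
#'
#' @param task a `grid_task`.
#' @param curriculum a `grid_curriculum` for that task.
#' @return character vector of lines.
#' @export
render_grid_curriculum <- function(task, curriculum) {
  loc <- task$locations
  study <- vapply(curriculum$order, function(i)
    sprintf("%s %s -> (%d, %d)", loc$color[i], loc$animal[i],
            loc$x[i], loc$y[i]), character(1))
  test <- vapply(curriculum$test, function(i)
    sprintf("%s %s -> ?", loc$color[i], loc$animal[i]), character(1))
  c(study, "---", test)
}
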