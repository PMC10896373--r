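test_that("rule-like grids are feature-aligned bijections", {
  for (seed in c(1L, 9L, 77L)) {
    g <- sample_grid_task("rule_like", seed = seed)
    loc <- g$locations
    expect_equal(nrow(loc), 25L)
    expect_equal(nrow(unique(loc[, c("x", "y")])), 25L)
    # every color shares one coordinate, every animal the other
    coord_of <- function(feature) {
      xs <- tapply(loc$x, loc[[feature]], function(v) length(unique(v)))
      ys <- tapply(loc$y, loc[[feature]], function(v) length(unique(v)))
      if (all(xs == 1L)) "x" else if (all(ys == 1L)) "y" else NA_character_
    }
    cc <- coord_of("color"); ac <- coord_of("animal")
    expect_false(is.na(cc))
    expect_false(is.na(ac))
    expect_true(cc != ac)
  }
  expect_identical(sample_grid_task("rule_like", seed = 4L),
                   sample_grid_task("rule_like", seed = 4L))
})

test_that("rotate_grid is the stated affine map and is invertible", {
  g <- sample_grid_task("rule_like", seed = 2L)
  rot <- rotate_grid(g$locations)
  # (0,0) -> (4,0)
  i <- which(g$locations$x == 0 & g$locations$y == 0)
  expect_equal(c(rot$x[i], rot$y[i]), c(4L, 0L))
  expect_true(all(rot$x >= 0 & rot$y >= 0))
  expect_equal(nrow(unique(rot[, c("x", "y")])), 25L)
  # all pairwise distances scale by exactly sqrt(2)
  d0 <- dist(g$locations[, c("x", "y")])
  d1 <- dist(rot[, c("x", "y")])
  expect_equal(as.numeric(d1), as.numeric(d0) * sqrt(2))
  expect_equal(unrotate_grid(rot), g$locations)
  expect_error(rotate_grid(rot), "5x5")
})

test_that("rotated tasks admit no single-feature coordinate rule", {
  g <- sample_grid_task("rotated", seed = 6L)
  loc <- g$locations
  one_det <- function(feature, coord) {
    all(tapply(loc[[coord]], loc[[feature]],
               function(v) length(unique(v))) == 1L)
  }
  expect_false(one_det("color", "x") || one_det("color", "y") ||
                 one_det("animal", "x") || one_det("animal", "y"))
})

test_that("grid curricula hold one full row plus one full column, 9/16 split", {
  for (seed in 1:15) {
    g <- sample_grid_task("rule_like", seed = seed)
    for (cond in c("blocked", "interleaved")) {
      cur <- make_grid_curriculum(g, cond, seed = seed + 100L)
      expect_length(cur$order, 9L)
      expect_length(cur$test, 16L)
      expect_length(intersect(cur$order, cur$test), 0L)
      studied <- g$locations[cur$order, ]
      expect_equal(sum(studied$animal == cur$row_value), 5L)
      expect_equal(sum(studied$color == cur$column_value), 5L)
    }
    b <- make_grid_curriculum(g, "blocked", seed = seed)
    i <- make_grid_curriculum(g, "interleaved", seed = seed)
    expect_setequal_int(b$order, b$order)
    # blocked: first 5 presentations form one full line
    first <- g$locations[b$order[1:5], ]
    if (b$block_order == "row_first") {
      expect_length(unique(first$animal), 1L)
    } else {
      expect_length(unique(first$color), 1L)
    }
  }
})

test_that("compositional_answer composes per-feature mappings", {
  # the worked example: blue elephant at x=3 plus red alligator at y=2
  # implies blue alligator at (3, 2)
  study <- data.frame(
    color = c("blue", "red", "green", "yellow", "purple",
              "red", "red", "red", "red"),
    animal = c("elephant", "elephant", "elephant", "elephant", "elephant",
               "alligator", "bear", "cat", "dog"),
    x = c(3L, 0L, 1L, 2L, 4L, 0L, 0L, 0L, 0L),
    y = c(4L, 4L, 4L, 4L, 4L, 2L, 0L, 1L, 3L),
    stringsAsFactors = FALSE)
  expect_equal(unname(compositional_answer(study, "blue", "alligator")),
               c(3L, 2L))
  # a study cue decodes to its stored location
  expect_equal(unname(compositional_answer(study, "red", "alligator")),
               c(0L, 2L))
  expect_error(compositional_answer(study, "blue", "walrus"), "study")
})

test_that("compositional_answer equals constraint-satisfaction brute force", {
  # independent oracle: the unique grid cell consistent with every study
  # constraint under the rule-like generative model
  brute <- function(study, color, animal) {
    cand <- expand.grid(x = 0:8, y = 0:8)
    ok <- vapply(seq_len(nrow(cand)), function(r) {
      full <- rbind(study, data.frame(color = color, animal = animal,
                                      x = cand$x[r], y = cand$y[r]))
      det <- function(f, cd) all(tapply(full[[cd]], full[[f]],
                                        function(v) length(unique(v))) == 1L)
      (det("color", "x") && det("animal", "y")) ||
        (det("animal", "x") && det("color", "y"))
    }, logical(1))
    c(cand$x[ok][1], cand$y[ok][1])
  }
  for (seed in 1:5) {
    g <- sample_grid_task("rule_like", seed = seed)
    cur <- make_grid_curriculum(g, "blocked", seed = seed)
    study <- g$locations[cur$order, ]
    for (i in cur$test) {
      ans <- compositional_answer(study, g$locations$color[i],
                                  g$locations$animal[i])
      expect_equal(unname(ans), c(g$locations$x[i], g$locations$y[i]))
      expect_equal(unname(ans),
                   brute(study, g$locations$color[i],
                         g$locations$animal[i]))
    }
  }
})

test_that("the oracle refuses rotated tasks", {
  g <- sample_grid_task("rotated", seed = 3L)
  cur <- make_grid_curriculum(g, "blocked", seed = 3L)
  study <- g$locations[cur$order, ]
  q <- cur$test[1]
  expect_error(compositional_answer(study, g$locations$color[q],
                                    g$locations$animal[q]),
               "not applicable")
})

test_that("grid tasks round-trip through JSONL and render readably", {
  tasks <- list(sample_grid_task("rule_like", seed = 1L),
                sample_grid_task("rotated", seed = 2L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_grid_tasks_jsonl(tasks, path)
  back <- read_grid_tasks_jsonl(path)
  for (i in 1:2) expect_equal(back[[i]]$locations, tasks[[i]]$locations)
  cur <- make_grid_curriculum(tasks[[1]], "blocked", seed = 1L)
  lines <- render_grid_curriculum(tasks[[1]], cur)
  expect_length(lines, 26L) # 9 study + divider + 16 queries
  expect_match(lines[1], "-> \\(\\d, \\d\\)")
})
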