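test_that("exact_match implements the all-tokens-correct rule", {
  expect_equal(exact_match(matrix(c(1, 2, 3), 3), matrix(c(1, 2, 3), 3)), 1)
  # a 2-token answer with one wrong token scores 0 for that query
  pred <- rbind(c(1, 2), c(3, 5))
  targ <- rbind(c(1, 2), c(3, 4))
  expect_equal(exact_match(pred, targ), 0.5)
  expect_equal(exact_match(c(1, 2, 3, 9), c(1, 2, 3, 4)), 0.75)
  expect_error(exact_match(matrix(nrow = 0, ncol = 1),
                           matrix(nrow = 0, ncol = 1)), "undefined")
})

make_traj <- function(acc_by_step) {
  # two groups A/B, blocks of 2 steps: A trained in block 1, B in block 2
  steps <- seq_along(acc_by_step$A)
  block <- (steps - 1L) %/% 2L + 1L
  trained <- ifelse(block %% 2L == 1L, "A", "B")
  d <- do.call(rbind, lapply(steps, function(s) {
    data.frame(step = s, block = block[s], trained_group = trained[s],
               metric = c("acc_A", "acc_B"),
               value = c(acc_by_step$A[s], acc_by_step$B[s]))
  }))
  attr(d, "groups") <- c("A", "B")
  attr(d, "gradient_curriculum") <- "blocked"
  d
}

test_that("forgetting_index measures the drop across the subsequent block", {
  flat <- make_traj(list(A = rep(0.8, 4), B = rep(0.5, 4)))
  fi <- forgetting_index(flat)
  expect_equal(unname(fi["A"]), 0)
  # A reaches 0.9 at the end of its block then collapses to 0.2
  drop <- make_traj(list(A = c(0.7, 0.9, 0.4, 0.2), B = c(0, 0, 0.5, 1)))
  expect_equal(unname(forgetting_index(drop)["A"]), 0.7)
  inter <- flat
  attr(inter, "gradient_curriculum") <- "interleaved"
  expect_error(forgetting_index(inter), "undefined")
})

test_that("identical cells give a null interaction; planted crossovers are detected", {
  cells <- expand.grid(curriculum = c("blocked", "interleaved"),
                       rotation = c("rule_like", "rotated"),
                       seed = 1:5, stringsAsFactors = FALSE)
  flat <- transform(cells, accuracy = 0.7)
  eff <- curriculum_effects_test(flat, n_perm = 200L, seed = 1L)
  f_inter <- eff$anova$F[eff$anova$term == "curriculum:rotation"]
  expect_true(is.na(f_inter) || f_inter < 1e-10)
  expect_gt(eff$interaction_p_permutation, 0.5)

  # planted crossover: means 0.9/0.6 vs 0.6/0.9, sd 0.05, n = 10 per cell
  set.seed(42)
  planted <- expand.grid(curriculum = c("blocked", "interleaved"),
                         rotation = c("rule_like", "rotated"),
                         rep = 1:10, stringsAsFactors = FALSE)
  mu <- with(planted, ifelse((curriculum == "blocked") ==
                               (rotation == "rule_like"), 0.9, 0.6))
  planted$accuracy <- rnorm(nrow(planted), mu, 0.05)
  eff2 <- curriculum_effects_test(planted, n_perm = 2000L, seed = 7L)
  expect_lt(eff2$anova$p[eff2$anova$term == "curriculum:rotation"], 0.001)
  expect_lt(eff2$interaction_p_permutation, 0.001)
  expect_gt(eff2$blocked_minus_interleaved[["rule_like"]], 0)
  expect_lt(eff2$blocked_minus_interleaved[["rotated"]], 0)
})

test_that("permutation and parametric interaction p-values agree within 2x", {
  # moderate planted effect so p lands inside (0.001, 0.5)
  set.seed(3)
  d <- expand.grid(curriculum = c("blocked", "interleaved"),
                   rotation = c("rule_like", "rotated"),
                   rep = 1:6, stringsAsFactors = FALSE)
  mu <- with(d, ifelse((curriculum == "blocked") ==
                         (rotation == "rule_like"), 0.75, 0.65))
  d$accuracy <- rnorm(nrow(d), mu, 0.08)
  eff <- curriculum_effects_test(d, n_perm = 4000L, seed = 11L)
  p_par <- eff$anova$p[eff$anova$term == "curriculum:rotation"]
  p_perm <- eff$interaction_p_permutation
  expect_gt(p_par, 0.001); expect_lt(p_par, 0.5)
  expect_lt(max(p_par, p_perm) / min(p_par, p_perm), 2)
})

test_that("symmetrically relabelled designs keep the same interaction p", {
  set.seed(5)
  d <- expand.grid(curriculum = c("blocked", "interleaved"),
                   rotation = c("rule_like", "rotated"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$accuracy <- rnorm(nrow(d), 0.7, 0.1)
  eff1 <- curriculum_effects_test(d, n_perm = 500L, seed = 2L)
  d2 <- d
  d2$curriculum <- ifelse(d$curriculum == "blocked", "interleaved",
                          "blocked")
  d2$rotation <- ifelse(d$rotation == "rule_like", "rotated", "rule_like")
  eff2 <- curriculum_effects_test(d2, n_perm = 500L, seed = 2L)
  expect_equal(eff1$anova$F[eff1$anova$term == "curriculum:rotation"],
               eff2$anova$F[eff2$anova$term == "curriculum:rotation"])
})

test_that("empty design cells are rejected", {
  d <- data.frame(curriculum = c("blocked", "blocked"),
                  rotation = c("rule_like", "rotated"),
                  accuracy = c(0.5, 0.6))
  expect_error(curriculum_effects_test(d), "design error")
})

test_that("retention of an untrained model sits at the chance floor", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 8L)
  cur <- make_grid_curriculum(g, "blocked", seed = 8L)
  accs <- vapply(1:8, function(s) {
    m <- init_model(tiny_config(), seed = s)
    retention_eval(m, g, cur, vb)
  }, numeric(1))
  # 8 models x 9 two-token queries; chance ~ (1/21)^2 per query.
  # an untrained model is not exactly uniform, so allow a loose ceiling
  expect_lt(mean(accs), 0.15)
})

test_that("retention_eval does not touch the parameters", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 9L)
  cur <- make_grid_curriculum(g, "blocked", seed = 9L)
  m <- init_model(tiny_config(), seed = 1L)
  before <- m$params
  invisible(retention_eval(m, g, cur, vb))
  expect_identical(m$params, before)
})
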