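test_that("configs enforce the architectural contracts", {
  cfg <- model_config("category")
  expect_equal(cfg$n_layers, 4L)
  expect_equal(cfg$n_heads, 8L)
  expect_equal(cfg$hidden_size, 64L)
  expect_equal(cfg$dropout, 0)
  expect_equal(cfg$ffn_size, 2L * cfg$hidden_size)
  cfg2 <- model_config("compositional")
  expect_equal(cfg2$n_layers, 12L)
  expect_equal(cfg2$dropout, 0.1)
  expect_error(model_config("category", hidden_size = 30L, n_heads = 8L),
               "divide")
})

test_that("initialization is seeded and the parameter count matches the closed form", {
  cfg <- model_config("compositional", "desk", n_layers = 2L,
                      hidden_size = 16L, n_heads = 4L, dropout = 0,
                      tie_embeddings = FALSE, positional = "learned")
  m1 <- init_model(cfg, seed = 5L)
  m2 <- init_model(cfg, seed = 5L)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(cfg, seed = 6L)
  expect_false(identical(m1$params, m3$params))

  h <- cfg$hidden_size; f <- cfg$ffn_size; dv <- cfg$d_v
  per_layer <- 4L * (h * h + h) +       # q, k, v, o projections
    2L * 2L * h +                       # two layernorms
    (h * f + f) + (f * h + h)           # feedforward
  expected <- dv * h + cfg$max_sequence_length * h +  # embeddings
    cfg$n_layers * per_layer +
    2L * h +                            # final layernorm
    h * dv + dv                         # output projection
  expect_equal(param_count(m1), expected)
  expect_equal(length(m1$params$layers), cfg$n_layers)
})

test_that("forward outputs normalized distributions and respects determinism", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 1L)
  cur <- make_grid_curriculum(g, "blocked", seed = 1L)
  eps <- lapply(1:5, function(i) encode_episode(g, cur, i, vb))
  m <- init_model(tiny_config(), seed = 1L)
  pr <- model_forward(m, eps, vb)
  expect_equal(dim(pr), c(2L, vb$n, 5L))
  expect_true(all(abs(apply(pr, c(1, 3), sum) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  expect_identical(greedy_decode(m, eps, vb), greedy_decode(m, eps, vb))
})

test_that("causal masking: outputs are invariant to future tokens", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 2L)
  cur <- make_grid_curriculum(g, "blocked", seed = 2L)
  ep <- encode_episode(g, cur, 3L, vb)
  m <- init_model(tiny_config(), seed = 2L)
  bt <- episode_batch(list(ep), vb)
  lg1 <- iclsim:::.tf_full_logits(m$params, unclass(m$config), bt$tokens,
                                  NULL)[[1]]
  tok2 <- bt$tokens
  tok2[1, ncol(tok2)] <- (tok2[1, ncol(tok2)] + 1L) %% vb$n # perturb last
  lg2 <- iclsim:::.tf_full_logits(m$params, unclass(m$config), tok2,
                                  NULL)[[1]]
  T_len <- ncol(bt$tokens)
  expect_equal(lg1[seq_len(T_len - 1L), ], lg2[seq_len(T_len - 1L), ],
               tolerance = 1e-12)
})

test_that("p_a = 0 matches the unablated forward; p_a = 1 erases the context", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 3L)
  cur <- make_grid_curriculum(g, "blocked", seed = 3L)
  eps <- lapply(1:4, function(i) encode_episode(g, cur, i, vb))
  m <- init_model(tiny_config(), seed = 3L)
  p0 <- model_forward(m, eps, vb, ablation = ablation_spec(0, seed = 1L))
  pn <- model_forward(m, eps, vb)
  expect_equal(p0, pn, tolerance = 1e-12)
  # under p_a = 1 the query outputs are invariant to replacing the context
  # with a different task's study set
  p1 <- model_forward(m, eps, vb, ablation = ablation_spec(1, seed = 1L))
  g2 <- sample_grid_task("rule_like", seed = 33L)
  cur2 <- make_grid_curriculum(g2, "blocked", seed = 33L)
  eps2 <- lapply(eps, function(ep) {
    ep2 <- encode_episode(g2, cur2, 1L, vb)
    ep$context <- ep2$context
    ep
  })
  p1b <- model_forward(m, eps2, vb, ablation = ablation_spec(1, seed = 2L))
  expect_equal(p1, p1b, tolerance = 1e-10)
})

test_that("greedy decoding follows a rigged output head", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 4L)
  cur <- make_grid_curriculum(g, "blocked", seed = 4L)
  eps <- lapply(1:3, function(i) encode_episode(g, cur, i, vb))
  m <- init_model(tiny_config(), seed = 4L)
  t_id <- token_id <- 12L # some coordinate token
  m$params$bu[] <- 0
  m$params$bu[t_id + 1L] <- 100 # overwhelm the logits
  preds <- greedy_decode(m, eps, vb)
  expect_true(all(preds == t_id))
})

test_that("evaluation-mode calls leave parameters bitwise unchanged", {
  vb <- vocab_compositional()
  g <- sample_grid_task("rule_like", seed = 5L)
  cur <- make_grid_curriculum(g, "blocked", seed = 5L)
  m <- init_model(tiny_config(), seed = 5L)
  before <- m$params
  fs <- few_shot_eval(m, list(g), "blocked", vb, seed = 1L)
  invisible(model_forward(m, list(encode_episode(g, cur, 1L, vb)), vb))
  expect_identical(m$params, before)
  expect_true(all(fs$acc_overall >= 0 & fs$acc_overall <= 1))
})

test_that("overlong sequences raise a length error", {
  vb <- vocab_compositional()
  cfg <- tiny_config()
  cfg$max_sequence_length <- 10L
  m <- init_model(cfg, seed = 1L)
  g <- sample_grid_task("rule_like", seed = 6L)
  cur <- make_grid_curriculum(g, "blocked", seed = 6L)
  expect_error(model_forward(m, list(encode_episode(g, cur, 1L, vb)), vb),
               "exceeds")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- init_model(tiny_config(), seed = 7L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$n_layers, m$config$n_layers)
})

test_that("ablation_spec validates its arguments", {
  expect_error(ablation_spec(1.5), "p_a")
  expect_error(ablation_spec(-0.1), "p_a")
  expect_error(ablation_spec(0.5, mode = "noise"), "hook")
  expect_equal(ablation_spec(0.3)$p_a, 0.3)
})
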