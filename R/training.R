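## Optimizer -----------------------------------------------------------------

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# one Adam step; returns params, state, and the L1 norm of the applied update
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd_norm <- 0
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      delta <- lr * mhat / (sqrt(vhat) + eps)
      upd_norm <<- upd_norm + sum(abs(delta))
      list(p = p - delta, m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t),
       upd_norm = upd_norm)
}

## Seed derivation ------------------------------------------------------------

# deterministic 31-bit child seeds from a parent seed and a stream label
derive_seed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else as.numeric(x)
  }, numeric(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(s %/% 1 + 1)
}

## Configurations -------------------------------------------------------------

#' Metalearning configuration
#'
#' Full-scale defaults follow the simulation settings: 12,000 training
#' tasks, 100 validation and 10 test tasks, batch size 256, Adam with
#' cross-entropy loss; 20 epochs at learning rate 1e-4 for the category
#' family, 500 epochs at 1e-3 for the compositional family. The
#' metalearning distribution is rule-like and blocked by default. Desk
#' scale reduces the task count and epochs so the qualitative phenomena can
#' be checked in minutes on one CPU.
#'
#' @param family `"category"` or `"compositional"`.
#' @param scale `"full"` or `"desk"`.
#' @param n_train_tasks,n_val_tasks,n_test_tasks,epochs,learning_rate,batch_size
#'   optional overrides.
#' @param distribution_rotation,distribution_curriculum the task distribution
#'   condition (defaults: rule-like, blocked).
#' @param query_policy `"mixed"` (queries uniform over all items, train and
#'   test equally likely) or `"train_only"`.
#' @param space feature space for the category family.
#' @export
meta_train_config <- function(family = c("category", "compositional"),
                              scale = c("full", "desk"),
                              n_train_tasks = NULL, n_val_tasks = NULL,
                              n_test_tasks = NULL, epochs = NULL,
                              learning_rate = NULL, batch_size = 256L,
                              distribution_rotation = "rule_like",
                              distribution_curriculum = "blocked",
                              query_policy = c("mixed", "train_only"),
                              context_supervision = FALSE,
                              val_every = NULL,
                              space = NULL) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  query_policy <- match.arg(query_policy)
  # desk-scale category tasks draw from a reduced dimension pool so the
  # per-token embeddings get enough updates within the desk step budget
  if (is.null(space))
    space <- if (family == "category" && scale == "desk")
      feature_space(30L) else feature_space()
  full <- list(n_train_tasks = 12000L, n_val_tasks = 100L,
               n_test_tasks = 10L,
               epochs = if (family == "category") 20L else 500L,
               learning_rate = if (family == "category") 1e-4 else 1e-3)
  desk <- list(n_train_tasks = 2000L, n_val_tasks = 12L, n_test_tasks = 10L,
               epochs = if (family == "category") 5L else 240L,
               learning_rate = full$learning_rate)
  d <- if (scale == "full") full else desk
  structure(list(
    family = family, scale = scale,
    n_train_tasks = as.integer(n_train_tasks %||% d$n_train_tasks),
    n_val_tasks = as.integer(n_val_tasks %||% d$n_val_tasks),
    n_test_tasks = as.integer(n_test_tasks %||% d$n_test_tasks),
    epochs = as.integer(epochs %||% d$epochs),
    learning_rate = learning_rate %||% d$learning_rate,
    batch_size = as.integer(batch_size),
    distribution_rotation = match.arg(distribution_rotation,
                                      c("rule_like", "rotated")),
    distribution_curriculum = match.arg(distribution_curriculum,
                                        c("blocked", "interleaved")),
    query_policy = query_policy,
    context_supervision = isTRUE(context_supervision),
    val_every = as.integer(val_every %||% (if (scale == "desk") 55L else 1L)),
    space = space),
    class = "meta_train_config")
}

#' Task-specific (finetuning) configuration
#'
#' Full-scale learning rates follow the simulation settings (1e-5 category,
#' 1e-4 compositional); the batch size equals the number of queries in a
#' block (32 category, 5 compositional). Blocked finetuning alternates `N`
#' gradient steps on queries from one stimulus group with `N` steps on the
#' other, for `n_block_alternations` alternations; interleaved draws mixed
#' batches for the same number of steps. Desk scale raises the learning
#' rate (5e-3 category, 3e-3 compositional -- the largest rates at which
#' memorization is stable for the desk models) and runs 30 alternations so
#' from-scratch in-weight learning converges within a few hundred steps.
#'
#' @param family `"category"` or `"compositional"`.
#' @param scale `"full"` or `"desk"`.
#' @param learning_rate,batch_size,N,n_block_alternations optional overrides.
#' @param gradient_curriculum `NULL` (congruent with the context curriculum)
#'   or `"blocked"`/`"interleaved"` for incongruent combinations.
#' @param blocked_batch `"group"`: a blocked batch holds the current group's
#'   study queries once; `"repeat"`: the group is repeated to fill
#'   `batch_size` queries.
#' @param freeze_weights if `TRUE` the run is evaluation-only and
#'   [finetune_task()] refuses it.
#' @param eval_every record trajectory metrics every this many steps.
#' @export
finetune_config <- function(family = c("category", "compositional"),
                            scale = c("full", "desk"),
                            learning_rate = NULL, batch_size = NULL,
                            N = 10L, n_block_alternations = NULL,
                            gradient_curriculum = NULL,
                            blocked_batch = c("group", "repeat"),
                            freeze_weights = FALSE, eval_every = NULL) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  blocked_batch <- match.arg(blocked_batch)
  lr_full <- if (family == "category") 1e-5 else 1e-4
  lr_desk <- if (family == "category") 5e-3 else 3e-3
  lr <- learning_rate %||% (if (scale == "full") lr_full else lr_desk)
  n_block_alternations <- n_block_alternations %||%
    (if (scale == "full") 10L else 30L)
  eval_every <- eval_every %||% (if (scale == "full") 1L else 10L)
  bs <- as.integer(batch_size %||% (if (family == "category") 32L else 5L))
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  structure(list(family = family, scale = scale, learning_rate = lr,
                 batch_size = bs, N = N,
                 n_block_alternations = as.integer(n_block_alternations),
                 gradient_curriculum = gradient_curriculum,
                 blocked_batch = blocked_batch,
                 freeze_weights = isTRUE(freeze_weights),
                 eval_every = as.integer(eval_every)),
            class = "finetune_config")
}

## Task pre-encoding ----------------------------------------------------------

# Precompute everything needed to emit episodes for a task quickly:
# the ordered context ids, per-item query ids and target ids. Vectorized
# (id arithmetic for the category family) but verified against
# encode_episode in the test suite.
precompute_task <- function(task, curriculum, vocab) {
  if (inherits(task, "category_task")) {
    nv <- vocab$space$values_per_dim
    it <- task$items
    v1 <- (task$dims[1] - 1L) * nv + it$v1 - 1L
    v2 <- (task$dims[2] - 1L) * nv + it$v2 - 1L
    lab <- vocab$space$pool_size * nv + (it$label == "B")
    ord <- curriculum$order
    context <- as.integer(rbind(v1[ord], v2[ord], lab[ord]))
    qmat <- cbind(v1, v2)
    tmat <- matrix(as.integer(lab), ncol = 1L)
    split <- ifelse(seq_len(64L) %in% task$study, "study", "heldout")
    group <- it$label
    n_items <- 64L
  } else {
    loc <- task$locations
    ctok <- match(loc$color, vocab$tokens$token) - 1L
    atok <- match(loc$animal, vocab$tokens$token) - 1L
    xtok <- match(as.character(loc$x), vocab$tokens$token) - 1L
    ytok <- match(as.character(loc$y), vocab$tokens$token) - 1L
    ord <- curriculum$order
    context <- as.integer(rbind(ctok[ord], atok[ord], xtok[ord], ytok[ord]))
    qmat <- cbind(ctok, atok)
    tmat <- cbind(xtok, ytok)
    split <- ifelse(seq_len(25L) %in% curriculum$order, "study", "heldout")
    group <- rep("test", 25L)
    group[curriculum$order] <- curriculum$groups
    n_items <- 25L
  }
  dimnames(qmat) <- NULL
  dimnames(tmat) <- NULL
  storage.mode(qmat) <- "integer"
  storage.mode(tmat) <- "integer"
  list(context = context, qmat = qmat, tmat = tmat, split = split,
       group = group, n_items = n_items, n_context_full = length(context))
}

# Assemble a raw training batch from a precomputed task and query indices.
# Returns tokens/targets directly (fast path used by the training loops).
# With context_answers = TRUE the answer tokens inside the context (each
# study example's label / coordinates) are supervised as well: predicting
# the k-th study example's answer from the preceding ones is few-shot
# learning with k-1 shots, which is what makes ICL emerge during
# metalearning.
pre_batch <- function(pre, queries, vocab, stripped = FALSE,
                      context_answers = FALSE) {
  qm <- token_id(vocab, "<q>")
  pad <- token_id(vocab, "<pad>")
  n_t <- ncol(pre$tmat)
  ctx <- if (stripped) rep(pad, pre$n_context_full) else pre$context
  base <- c(ctx, qm)
  rows <- lapply(queries, function(i) {
    tg <- pre$tmat[i, ]
    c(base, pre$qmat[i, ], tg[seq_len(n_t - 1L)])
  })
  tokens <- do.call(rbind, rows)
  storage.mode(tokens) <- "integer"
  q_end <- length(base) + ncol(pre$qmat)
  target_pos <- (q_end - 1L) + seq_len(n_t) - 1L
  targets <- pre$tmat[queries, , drop = FALSE]
  if (context_answers) {
    run <- vocab$layout$run_length
    n_ex <- pre$n_context_full %/% run
    starts <- (seq_len(n_ex) - 1L) * run          # 0-based run starts
    ans_off <- seq.int(run - n_t, run - 1L)       # answer slots in a run
    ctx_pos <- as.integer(outer(ans_off - 1L, starts, `+`)) # predictor pos
    ctx_ids <- pre$context[as.integer(outer(ans_off, starts, `+`)) + 1L]
    target_pos <- c(ctx_pos, target_pos)
    targets <- cbind(matrix(rep(ctx_ids, each = length(queries)),
                            nrow = length(queries)), targets)
  }
  storage.mode(targets) <- "integer"
  keymask <- NULL
  if (stripped) {
    keymask <- matrix(1, nrow(tokens), ncol(tokens))
    keymask[, seq_len(pre$n_context_full)] <- 0
  }
  list(tokens = tokens, target_pos = as.integer(target_pos),
       targets = targets, keymask = keymask)
}

# sample a key mask for a raw batch under example-dropping ablation
ablate_keymask <- function(bt, pre, vocab, p_a) {
  run <- vocab$layout$run_length
  n_ex <- pre$n_context_full %/% run
  km <- matrix(1, nrow(bt$tokens), ncol(bt$tokens))
  for (b in seq_len(nrow(km))) {
    drop <- stats::runif(n_ex) < p_a
    for (e in which(drop)) km[b, ((e - 1L) * run + 1L):(e * run)] <- 0
  }
  km
}

decode_raw <- function(model, bt) {
  n_t <- ncol(bt$targets)
  preds <- matrix(NA_integer_, nrow(bt$tokens), n_t)
  tokens <- bt$tokens
  for (k in seq_len(n_t)) {
    pos <- bt$target_pos[k]
    out <- .tf_batch(model$params, unclass(model$config), tokens,
                     bt$keymask, pos, NULL, FALSE, FALSE, 0L)
    pred <- apply(out$logits[1, , , drop = FALSE], 3, which.max) - 1L
    preds[, k] <- pred
    if (k < n_t) tokens[, pos + 2L] <- pred
  }
  preds
}

## Metalearning ---------------------------------------------------------------

sample_family_task <- function(family, rotation, space, seed) {
  if (family == "category")
    sample_category_task(space, rotation, seed = seed)
  else sample_grid_task(rotation, seed = seed)
}

#' Metalearn: induce in-context learning by training across tasks
#'
#' Trains the network on episodes drawn from a distribution of freshly
#' sampled tasks (one query per task per epoch, drawn under the query
#' policy), with cross-entropy loss on the answer tokens and Adam. Each
#' task keeps a fixed study curriculum sampled from the distribution
#' condition. Validation few-shot exact-match is computed each epoch on
#' held-out tasks and the best-validation parameters are returned.
#'
#' @param config a [model_config()].
#' @param meta a [meta_train_config()].
#' @param seed integer master seed; all task sampling, initialization,
#'   shuffling and dropout derive from it.
#' @param verbose print per-epoch progress.
#' @return list: `model` (best validation checkpoint), `final_model`,
#'   `history` (per-epoch `train_loss`, `val_acc`), `val_tasks`,
#'   `test_tasks` (held-out tasks for downstream evaluation).
#' @export
metalearn <- function(config, meta, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"),
            inherits(meta, "meta_train_config"))
  if (config$family != meta$family)
    stop("config error: model and metalearning families disagree")
  vocab <- build_vocab(meta$family, meta$space)
  if (vocab$n != config$d_v)
    stop("config error: model d_v does not match the family vocabulary")

  pre_list <- vector("list", meta$n_train_tasks)
  for (i in seq_len(meta$n_train_tasks)) {
    tk <- sample_family_task(meta$family, meta$distribution_rotation,
                             meta$space, derive_seed(seed, "task", i))
    cur <- if (meta$family == "category")
      make_curriculum(tk, meta$distribution_curriculum,
                      seed = derive_seed(seed, "cur", i))
    else make_grid_curriculum(tk, meta$distribution_curriculum,
                              seed = derive_seed(seed, "cur", i))
    pre_list[[i]] <- precompute_task(tk, cur, vocab)
  }
  val_tasks <- lapply(seq_len(meta$n_val_tasks), function(i)
    sample_family_task(meta$family, meta$distribution_rotation, meta$space,
                       derive_seed(seed, "val", i)))
  test_tasks <- lapply(seq_len(meta$n_test_tasks), function(i)
    sample_family_task(meta$family, meta$distribution_rotation, meta$space,
                       derive_seed(seed, "test", i)))

  model <- init_model(config, seed = derive_seed(seed, "init"))
  opt <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params)
  history <- data.frame()
  n_items <- pre_list[[1]]$n_items

  for (ep in seq_len(meta$epochs)) {
    ep_seed <- derive_seed(seed, "epoch", ep)
    order_queries <- withr::with_seed(ep_seed, {
      ord <- sample.int(meta$n_train_tasks)
      qs <- vapply(pre_list[ord], function(pre) {
        pool <- if (meta$query_policy == "mixed") seq_len(pre$n_items)
                else which(pre$split == "study")
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      list(ord = ord, qs = qs)
    })
    ep_loss <- 0; n_batches <- 0L
    starts <- seq(1L, meta$n_train_tasks, by = meta$batch_size)
    for (s in starts) {
      idx <- s:min(s + meta$batch_size - 1L, meta$n_train_tasks)
      rows <- lapply(seq_along(idx), function(j) {
        pre <- pre_list[[order_queries$ord[idx[j]]]]
        q <- order_queries$qs[idx[j]]
        pre_batch(pre, q, vocab,
                  context_answers = meta$context_supervision)
      })
      tokens <- do.call(rbind, lapply(rows, `[[`, "tokens"))
      targets <- do.call(rbind, lapply(rows, `[[`, "targets"))
      out <- .tf_batch(model$params, unclass(model$config), tokens, NULL,
                       rows[[1]]$target_pos, targets, TRUE, TRUE,
                       derive_seed(seed, "drop", ep, s))
      st <- adam_step(model$params, out$grads, opt, meta$learning_rate)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + out$loss; n_batches <- n_batches + 1L
    }
    if (ep %% meta$val_every == 0L || ep == meta$epochs) {
      val <- few_shot_eval(model, val_tasks, meta$distribution_curriculum,
                           vocab, seed = derive_seed(seed, "valcur", ep))
      val_acc <- mean(val$acc_overall)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / n_batches,
                                           val_acc = val_acc))
      if (val_acc >= best$acc) best <- list(acc = val_acc,
                                            params = model$params)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val acc %.3f", ep,
                        ep_loss / n_batches, val_acc))
    }
  }
  best_model <- model
  best_model$params <- best$params
  list(model = best_model, final_model = model, history = history,
       val_tasks = val_tasks, test_tasks = test_tasks, vocab = vocab)
}

## Frozen-weight evaluation ---------------------------------------------------

#' Few-shot evaluation with frozen weights
#'
#' For each task, builds a study curriculum under `curriculum_condition`,
#' presents every item of the task as a query against that context, and
#' scores greedy decoding by exact match. No parameter is changed: all
#' learning is in-context.
#'
#' @param model an `icl_model`.
#' @param tasks list of tasks (unseen during metalearning).
#' @param curriculum_condition `"blocked"` or `"interleaved"`.
#' @param vocab the family vocabulary.
#' @param ablation optional [ablation_spec()].
#' @param seed integer seed for the curricula (and ablation masks).
#' @return data frame, one row per task: `acc_overall`, `acc_study`,
#'   `acc_heldout`, `n_queries`, `chance`, condition tags.
#' @export
few_shot_eval <- function(model, tasks, curriculum_condition, vocab,
                          ablation = NULL, seed = 1L) {
  rows <- lapply(seq_along(tasks), function(i) {
    task <- tasks[[i]]
    cur <- if (inherits(task, "category_task"))
      make_curriculum(task, curriculum_condition,
                      seed = derive_seed(seed, "fscur", i))
    else make_grid_curriculum(task, curriculum_condition,
                              seed = derive_seed(seed, "fscur", i))
    pre <- precompute_task(task, cur, vocab)
    bt <- pre_batch(pre, seq_len(pre$n_items), vocab)
    if (!is.null(ablation) && ablation$p_a > 0)
      bt$keymask <- withr::with_seed(derive_seed(seed, "abl", i),
                                     ablate_keymask(bt, pre, vocab,
                                                    ablation$p_a))
    preds <- decode_raw(model, bt)
    correct <- rowSums(preds == bt$targets) == ncol(bt$targets)
    is_study <- pre$split == "study"
    data.frame(task = i, rotation = task$condition,
               curriculum = curriculum_condition,
               acc_overall = mean(correct),
               acc_study = mean(correct[is_study]),
               acc_heldout = mean(correct[!is_study]),
               n_queries = length(correct), chance = 1 / vocab$n)
  })
  do.call(rbind, rows)
}

## Task-specific training -----------------------------------------------------

#' Finetune on a single task (in-weight learning, possibly on top of ICL)
#'
#' Supervision comes only from study-example queries (the model never
#' receives feedback on held-out items, emulating the human studies). In
#' the blocked gradient schedule the model takes `N` Adam steps on queries
#' from one stimulus group, then `N` on the other, alternating; the
#' interleaved schedule draws mixed batches. The study context (ordered by
#' the context curriculum) is present in every input. After every gradient
#' step the trajectory records, with weights momentarily frozen, greedy
#' exact-match accuracy per group and on the held-out items.
#'
#' @param model starting `icl_model` (random or metalearned).
#' @param task the task to learn.
#' @param curriculum its context curriculum (also defines the groups).
#' @param config a [finetune_config()].
#' @param vocab the family vocabulary.
#' @param ablation optional [ablation_spec()] applied to both the training
#'   inputs and the trajectory evaluations.
#' @param seed integer seed (batch order, ablation masks, dropout).
#' @return list: `model` (final state), `trajectory` (tidy data frame),
#'   `cumulative_loss`, `update_norm` (summed L1 parameter movement),
#'   `steps_to_criterion` (first step with study accuracy >= 0.9, `NA` if
#'   never reached).
#' @export
finetune_task <- function(model, task, curriculum, config, vocab,
                          ablation = NULL, seed = 1L) {
  stopifnot(inherits(config, "finetune_config"))
  if (config$freeze_weights)
    stop("contract error: freeze_weights = TRUE cannot be finetuned")
  pre <- precompute_task(task, curriculum, vocab)
  study_idx <- which(pre$split == "study")
  groups <- pre$group[study_idx]
  # groups ordered by first appearance in the curriculum
  first_app <- vapply(unique(groups), function(g)
    min(match(study_idx[groups == g], curriculum$order)), numeric(1))
  group_levels <- unique(groups)[order(first_app)]

  grad_cur <- config$gradient_curriculum %||% curriculum$condition
  n_steps <- config$N * config$n_block_alternations
  p_a <- if (!is.null(ablation)) ablation$p_a else 0

  eval_bt <- pre_batch(pre, seq_len(pre$n_items), vocab)
  traj <- vector("list", n_steps)
  cum_loss <- 0; upd_total <- 0
  opt <- adam_init(model$params)
  steps_to_crit <- NA_integer_

  for (step in seq_len(n_steps)) {
    phase <- ((step - 1L) %/% config$N) %% length(group_levels) + 1L
    block_id <- (step - 1L) %/% config$N + 1L
    step_seed <- derive_seed(seed, "ftstep", step)
    batch_queries <- withr::with_seed(step_seed, {
      if (grad_cur == "blocked") {
        pool <- study_idx[groups == group_levels[phase]]
        if (config$blocked_batch == "repeat" &&
            length(pool) < config$batch_size)
          sample(rep(pool, length.out = config$batch_size))
        else sample(pool)
      } else {
        sample(study_idx, min(config$batch_size, length(study_idx)))
      }
    })
    bt <- pre_batch(pre, batch_queries, vocab)
    if (p_a > 0)
      bt$keymask <- withr::with_seed(derive_seed(seed, "ftabl", step),
                                     ablate_keymask(bt, pre, vocab, p_a))
    out <- .tf_batch(model$params, unclass(model$config), bt$tokens,
                     bt$keymask, bt$target_pos, bt$targets, TRUE, TRUE,
                     derive_seed(seed, "ftdrop", step))
    st <- adam_step(model$params, out$grads, opt, config$learning_rate)
    model$params <- st$params; opt <- st$state
    cum_loss <- cum_loss + out$loss
    upd_total <- upd_total + st$upd_norm

    if (step %% config$eval_every == 0L || step == n_steps) {
      ebt <- eval_bt
      if (p_a > 0)
        ebt$keymask <- withr::with_seed(derive_seed(seed, "evabl", step),
                                        ablate_keymask(ebt, pre, vocab, p_a))
      preds <- decode_raw(model, ebt)
      correct <- rowSums(preds == ebt$targets) == ncol(ebt$targets)
      is_study <- pre$split == "study"
      acc_study <- mean(correct[is_study])
      if (is.na(steps_to_crit) && acc_study >= 0.9)
        steps_to_crit <- step
      rows <- lapply(group_levels, function(g) {
        sel <- is_study & pre$group == g
        data.frame(step = step, block = block_id,
                   trained_group = group_levels[phase],
                   metric = paste0("acc_", g), value = mean(correct[sel]))
      })
      rows <- c(rows, list(
        data.frame(step = step, block = block_id,
                   trained_group = group_levels[phase],
                   metric = "acc_study", value = acc_study),
        data.frame(step = step, block = block_id,
                   trained_group = group_levels[phase],
                   metric = "acc_heldout",
                   value = mean(correct[!is_study])),
        data.frame(step = step, block = block_id,
                   trained_group = group_levels[phase],
                   metric = "loss", value = out$loss)))
      traj[[step]] <- do.call(rbind, rows)
    }
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  attr(trajectory, "groups") <- group_levels
  attr(trajectory, "gradient_curriculum") <- grad_cur
  list(model = model, trajectory = trajectory, cumulative_loss = cum_loss,
       update_norm = upd_total, steps_to_criterion = steps_to_crit,
       groups = group_levels)
}
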