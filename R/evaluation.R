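#' Exact-match accuracy
#'
#' A multi-token answer counts as correct only if every token matches.
#'
#' @param predictions integer matrix (or vector) of predicted token ids,
#'   one row per query.
#' @param targets matching matrix/vector of reference ids.
#' @return fraction of queries answered exactly.
#' @export
exact_match <- function(predictions, targets) {
  if (is.null(dim(predictions))) predictions <- cbind(predictions)
  if (is.null(dim(targets))) targets <- cbind(targets)
  if (nrow(predictions) == 0L) stop("undefined metric: no predictions")
  if (!all(dim(predictions) == dim(targets)))
    stop("predictions and targets must have the same shape")
  mean(rowSums(predictions == targets) == ncol(targets))
}

#' Per-group forgetting index of a blocked trajectory
#'
#' For each stimulus group g: accuracy on g at the end of g's own training
#' block minus accuracy on g at the end of the next block in which the
#' other group was trained. Positive values indicate catastrophic
#' forgetting. Undefined for interleaved trajectories.
#'
#' @param trajectory the tidy trajectory from [finetune_task()].
#' @return named numeric vector, one entry per group that has a subsequent
#'   other-group block.
#' @export
forgetting_index <- function(trajectory) {
  if (!identical(attr(trajectory, "gradient_curriculum"), "blocked"))
    stop("forgetting index undefined for interleaved trajectories")
  groups <- attr(trajectory, "groups")
  blocks <- sort(unique(trajectory$block))
  if (length(blocks) < 2L) stop("need at least 2 blocks")
  block_end <- function(b, metric) {
    d <- trajectory[trajectory$block == b & trajectory$metric == metric, ]
    d$value[which.max(d$step)]
  }
  block_group <- vapply(blocks, function(b)
    trajectory$trained_group[trajectory$block == b][1], character(1))
  out <- numeric(0)
  for (g in groups) {
    own <- blocks[block_group == g]
    other <- blocks[block_group != g]
    drops <- c()
    for (b in own) {
      nxt <- other[other > b]
      if (length(nxt) > 0)
        drops <- c(drops, block_end(b, paste0("acc_", g)) -
                     block_end(min(nxt), paste0("acc_", g)))
    }
    if (length(drops) > 0) out[g] <- drops[1]
  }
  out
}

#' Retention test: recall without context
#'
#' Queries the study items of a finetuned model with the context removed
#' ([strip_context()]), so that only information stored in the weights can
#' drive the answer. No parameters are updated.
#'
#' @param model the finetuned `icl_model`.
#' @param task the task it was finetuned on.
#' @param curriculum the curriculum used (defines the study set and the
#'   sequence geometry).
#' @param vocab the family vocabulary.
#' @return exact-match accuracy on the study items.
#' @export
retention_eval <- function(model, task, curriculum, vocab) {
  pre <- precompute_task(task, curriculum, vocab)
  study_idx <- which(pre$split == "study")
  bt <- pre_batch(pre, study_idx, vocab, stripped = TRUE)
  preds <- decode_raw(model, bt)
  exact_match(preds, bt$targets)
}

#' Flexibility-retention ablation sweep
#'
#' For each attention-ablation level `p_a` and each seed: (1) frozen-weight
#' few-shot accuracy of the metalearned model on fresh tasks under the
#' ablation; (2) a finetuning run under the same ablation, recording
#' steps-to-criterion (study accuracy >= 0.9), cumulative loss, and summed
#' parameter movement; (3) the retention test on the finetuned weights.
#'
#' @param model metalearned `icl_model`.
#' @param family `"category"` or `"compositional"`.
#' @param vocab the family vocabulary.
#' @param p_a_grid ablation levels (default `c(0, 0.2, 0.4, 0.6, 0.8)`).
#' @param n_seeds seeds per level (default 5).
#' @param rotation,curriculum_condition task condition for the sweep
#'   (defaults: rule-like, blocked -- the metalearning distribution).
#' @param finetune a [finetune_config()].
#' @param n_fewshot_tasks tasks per few-shot measurement.
#' @param space feature space (category family).
#' @param seed master seed.
#' @return data frame of class `sweep_result`, one row per `(p_a, seed)`.
#' @export
tradeoff_sweep <- function(model, family, vocab,
                           p_a_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                           n_seeds = 5L,
                           rotation = "rule_like",
                           curriculum_condition = "blocked",
                           finetune = finetune_config(family, "desk"),
                           n_fewshot_tasks = 5L,
                           space = feature_space(), seed = 1L) {
  stopifnot(all(p_a_grid >= 0 & p_a_grid <= 1))
  p_a_grid <- sort(p_a_grid)
  rows <- list()
  for (p_a in p_a_grid) {
    for (s in seq_len(n_seeds)) {
      sseed <- derive_seed(seed, "sweep", round(1000 * p_a), s)
      abl <- if (p_a > 0) ablation_spec(p_a) else NULL
      fs_tasks <- lapply(seq_len(n_fewshot_tasks), function(i)
        sample_family_task(family, rotation, space,
                           derive_seed(sseed, "fstask", i)))
      fs <- few_shot_eval(model, fs_tasks, curriculum_condition, vocab,
                          ablation = abl, seed = derive_seed(sseed, "fs"))
      task <- sample_family_task(family, rotation, space,
                                 derive_seed(sseed, "task"))
      cur <- if (family == "category")
        make_curriculum(task, curriculum_condition,
                        seed = derive_seed(sseed, "cur"))
      else make_grid_curriculum(task, curriculum_condition,
                                seed = derive_seed(sseed, "cur"))
      ft <- finetune_task(model, task, cur, finetune, vocab,
                          ablation = abl, seed = derive_seed(sseed, "ft"))
      ret <- retention_eval(ft$model, task, cur, vocab)
      rows[[length(rows) + 1L]] <- data.frame(
        p_a = p_a, seed = s,
        fewshot_acc = mean(fs$acc_overall),
        fewshot_study_acc = mean(fs$acc_study),
        steps_to_criterion = ft$steps_to_criterion,
        cumulative_loss = ft$cumulative_loss,
        update_norm = ft$update_norm,
        retention_acc = ret)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Curriculum-by-rotation effects table
#'
#' Two-way analysis of variance (curriculum x rotation, between-run) on
#' per-run accuracies, with a permutation cross-check of the interaction:
#' cell labels are permuted jointly and the interaction F statistic is
#' recomputed.
#'
#' @param reports data frame with columns `accuracy`, `curriculum`,
#'   `rotation` (>= 2 runs per cell).
#' @param n_perm permutation draws (default 2000).
#' @param seed seed for the permutation draw.
#' @return list of class `effects_table`: `anova` (term, F, p),
#'   `interaction_p_permutation`, `cell_means`, and the signed
#'   blocked-minus-interleaved differences per rotation.
#' @export
curriculum_effects_test <- function(reports, n_perm = 2000L, seed = 1L) {
  need <- c("accuracy", "curriculum", "rotation")
  if (!all(need %in% names(reports)))
    stop("reports must have columns accuracy, curriculum, rotation")
  reports$curriculum <- factor(reports$curriculum)
  reports$rotation <- factor(reports$rotation)
  tab <- table(reports$curriculum, reports$rotation)
  if (nlevels(reports$curriculum) < 2L || nlevels(reports$rotation) < 2L ||
      any(tab == 0))
    stop("design error: empty cell in curriculum x rotation")
  if (stats::var(reports$accuracy) < 1e-20) {
    # degenerate constant design: no effect of anything
    anova_df <- data.frame(
      term = c("curriculum", "rotation", "curriculum:rotation", "Residuals"),
      df = NA_integer_, F = c(0, 0, 0, NA), p = c(1, 1, 1, NA))
    cm <- stats::aggregate(accuracy ~ curriculum + rotation, reports, mean)
    diffs <- stats::setNames(rep(0, nlevels(reports$rotation)),
                             levels(reports$rotation))
    return(structure(list(anova = anova_df,
                          interaction_p_permutation = 1,
                          cell_means = cm,
                          blocked_minus_interleaved = diffs),
                     class = "effects_table"))
  }
  fit <- stats::aov(accuracy ~ curriculum * rotation, data = reports)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  anova_df <- data.frame(term = terms, df = an[["Df"]],
                         F = an[["F value"]], p = an[["Pr(>F)"]])
  f_inter <- function(d) {
    a <- summary(stats::aov(accuracy ~ curriculum * rotation, data = d))[[1]]
    f <- a[["F value"]][trimws(rownames(a)) == "curriculum:rotation"]
    if (length(f) == 0 || !is.finite(f)) 0 else f
  }
  f_obs <- f_inter(reports)
  perm_p <- withr::with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      d <- reports
      idx <- sample.int(nrow(d))
      d$curriculum <- d$curriculum[idx]
      d$rotation <- d$rotation[idx]
      if (f_inter(d) >= f_obs) cnt <- cnt + 1L
    }
    (cnt + 1) / (n_perm + 1)
  })
  cm <- stats::aggregate(accuracy ~ curriculum + rotation, reports, mean)
  diffs <- sapply(levels(reports$rotation), function(r) {
    b <- cm$accuracy[cm$curriculum == "blocked" & cm$rotation == r]
    i <- cm$accuracy[cm$curriculum == "interleaved" & cm$rotation == r]
    b - i
  })
  structure(list(anova = anova_df, interaction_p_permutation = perm_p,
                 cell_means = cm, blocked_minus_interleaved = diffs),
            class = "effects_table")
}

#' @export
print.effects_table <- function(x, ...) {
  cat("<effects_table>\n")
  print(x$anova, row.names = FALSE)
  cat(sprintf("interaction permutation p: %.4g\n",
              x$interaction_p_permutation))
  cat("blocked - interleaved by rotation:\n")
  print(x$blocked_minus_interleaved)
  invisible(x)
}

#' Export an effects table or sweep result
#' @param x an `effects_table` or `sweep_result`.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @export
export_results <- function(x, path_csv = NULL, path_json = NULL) {
  if (inherits(x, "effects_table")) {
    if (!is.null(path_csv)) utils::write.csv(x$anova, path_csv,
                                             row.names = FALSE)
    if (!is.null(path_json))
      jsonlite::write_json(list(anova = x$anova,
                                interaction_p_permutation =
                                  x$interaction_p_permutation,
                                cell_means = x$cell_means),
                           path_json, auto_unbox = TRUE, digits = NA)
  } else {
    if (!is.null(path_csv)) utils::write.csv(as.data.frame(x), path_csv,
                                             row.names = FALSE)
    if (!is.null(path_json))
      jsonlite::write_json(as.data.frame(x), path_json, auto_unbox = TRUE,
                           digits = NA)
  }
  invisible(x)
}
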