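preset_names <- c("fig2_iwl", "fig2_icl", "fig2_full", "fig3_iwl",
                  "fig3_icl", "fig3_full", "fig5_sweep", "smoke")

#' Validate and resolve an experiment configuration
#'
#' Fills unspecified keys with the reference defaults and rejects unknown
#' keys, out-of-range values, and contradictory combinations.
#'
#' @param raw named list (possibly empty) with any of: `family`, `scale`,
#'   `seed`, `n_seeds`, `p_a`, `meta` (list of [meta_train_config()]
#'   overrides), `finetune` (list of [finetune_config()] overrides),
#'   `model` (list of [model_config()] overrides).
#' @return resolved list with `model_config`, `meta_config`,
#'   `finetune_config` objects.
#' @export
validate_config <- function(raw = list()) {
  known <- c("family", "scale", "seed", "n_seeds", "p_a", "meta",
             "finetune", "model")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  family <- match.arg(raw$family %||% "category",
                      c("category", "compositional"))
  scale <- match.arg(raw$scale %||% "desk", c("full", "desk"))
  p_a <- raw$p_a %||% 0
  if (!is.numeric(p_a) || any(p_a < 0 | p_a > 1))
    stop("config error: p_a must lie in [0, 1]")
  if (isTRUE(raw$finetune$freeze_weights))
    stop("config error: freeze_weights contradicts finetuning")
  mc <- do.call(model_config,
                c(list(family = family, scale = scale), raw$model))
  meta <- do.call(meta_train_config,
                  c(list(family = family, scale = scale), raw$meta))
  ft <- do.call(finetune_config,
                c(list(family = family, scale = scale), raw$finetune))
  list(family = family, scale = scale, seed = as.integer(raw$seed %||% 1L),
       n_seeds = as.integer(raw$n_seeds %||% 3L), p_a = p_a,
       model_config = mc, meta_config = meta, finetune_config = ft)
}

run_conditions <- expand.grid(rotation = c("rule_like", "rotated"),
                              curriculum = c("blocked", "interleaved"),
                              stringsAsFactors = FALSE)

# one finetuning run per (rotation x curriculum x seed); model_fn supplies
# the starting state (fresh random or metalearned)
run_condition_grid <- function(model_fn, family, vocab, ft_config, n_seeds,
                               seed, space = feature_space()) {
  rows <- list()
  trajs <- list()
  for (ci in seq_len(nrow(run_conditions))) {
    rot <- run_conditions$rotation[ci]
    cur_cond <- run_conditions$curriculum[ci]
    for (s in seq_len(n_seeds)) {
      rseed <- derive_seed(seed, rot, cur_cond, s)
      task <- sample_family_task(family, rot, space,
                                 derive_seed(rseed, "task"))
      cur <- if (family == "category")
        make_curriculum(task, cur_cond, seed = derive_seed(rseed, "cur"))
      else make_grid_curriculum(task, cur_cond,
                                seed = derive_seed(rseed, "cur"))
      ft <- finetune_task(model_fn(rseed), task, cur, ft_config, vocab,
                          seed = derive_seed(rseed, "ft"))
      fin <- ft$trajectory[ft$trajectory$step == max(ft$trajectory$step), ]
      final_of <- function(m) fin$value[fin$metric == m]
      rows[[length(rows) + 1L]] <- data.frame(
        rotation = rot, curriculum = cur_cond, seed = s,
        accuracy = (final_of("acc_study") + final_of("acc_heldout")) / 2,
        acc_study = final_of("acc_study"),
        acc_heldout = final_of("acc_heldout"),
        cumulative_loss = ft$cumulative_loss,
        update_norm = ft$update_norm)
      trajs[[paste(rot, cur_cond, s, sep = "_")]] <- ft$trajectory
    }
  }
  list(summary = do.call(rbind, rows), trajectories = trajs)
}

#' Run a named experiment preset
#'
#' Presets reproduce the main simulation experiments: `fig2_*` are the
#' category-learning experiments (IWL-only from scratch, ICL few-shot after
#' metalearning, and the full ICL+IWL interaction), `fig3_*` the
#' compositional analogues, `fig5_sweep` the flexibility-retention ablation
#' sweep, and `smoke` a minutes-scale end-to-end self check. All outputs are
#' written as CSV plus a JSON manifest; every output is a pure function of
#' `(name, scale, seed)`.
#'
#' @param name one of `fig2_iwl`, `fig2_icl`, `fig2_full`, `fig3_iwl`,
#'   `fig3_icl`, `fig3_full`, `fig5_sweep`, `smoke`.
#' @param scale `"desk"` (reduced, minutes) or `"full"` (reference
#'   configuration; hours on one CPU).
#' @param seed integer master seed.
#' @param outdir output directory (created if missing).
#' @param n_seeds runs per condition cell.
#' @return the experiment manifest (invisibly), with a `results` attribute.
#' @export
run_preset <- function(name, scale = c("desk", "full"), seed = 1L,
                       outdir = tempfile("iclsim_"), n_seeds = 3L) {
  if (!name %in% preset_names)
    stop("usage error: unknown preset '", name, "'; expected one of: ",
         paste(preset_names, collapse = ", "))
  scale <- match.arg(scale)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  family <- if (grepl("^fig3|^fig5", name)) "compositional" else "category"
  cfg <- validate_config(list(family = family, scale = scale, seed = seed,
                              n_seeds = n_seeds))
  vocab <- build_vocab(family, cfg$meta_config$space)
  results <- list()

  if (name == "smoke") {
    smoke_results <- smoke_check(seed)
    utils::write.csv(smoke_results, file.path(outdir, "smoke.csv"),
                     row.names = FALSE)
    results$smoke <- smoke_results
  } else if (name %in% c("fig2_iwl", "fig3_iwl")) {
    grid <- run_condition_grid(
      function(s) init_model(cfg$model_config, seed = derive_seed(s, "init")),
      family, vocab, cfg$finetune_config, n_seeds, seed,
      cfg$meta_config$space)
    utils::write.csv(grid$summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    write_trajectories(grid$trajectories, outdir)
    results$summary <- grid$summary
  } else {
    ml <- metalearn(cfg$model_config, cfg$meta_config,
                    seed = derive_seed(seed, "meta"))
    utils::write.csv(ml$history, file.path(outdir, "metalearn_history.csv"),
                     row.names = FALSE)
    if (name %in% c("fig2_icl", "fig3_icl")) {
      fs <- do.call(rbind, lapply(seq_len(nrow(run_conditions)), function(ci) {
        rot <- run_conditions$rotation[ci]
        cc <- run_conditions$curriculum[ci]
        tasks <- lapply(seq_len(max(n_seeds, 3L)), function(i)
          sample_family_task(family, rot, cfg$meta_config$space,
                             derive_seed(seed, "fstask", ci, i)))
        r <- few_shot_eval(ml$model, tasks, cc, vocab,
                           seed = derive_seed(seed, "fs", ci))
        r
      }))
      utils::write.csv(fs, file.path(outdir, "few_shot.csv"),
                       row.names = FALSE)
      results$few_shot <- fs
    } else if (name %in% c("fig2_full", "fig3_full")) {
      grid <- run_condition_grid(function(s) ml$model, family, vocab,
                                 cfg$finetune_config, n_seeds, seed,
                                 cfg$meta_config$space)
      grid$summary$accuracy <- (grid$summary$acc_study +
                                  grid$summary$acc_heldout) / 2
      eff <- curriculum_effects_test(grid$summary,
                                     seed = derive_seed(seed, "perm"))
      utils::write.csv(grid$summary, file.path(outdir, "summary.csv"),
                       row.names = FALSE)
      write_trajectories(grid$trajectories, outdir)
      export_results(eff, file.path(outdir, "effects.csv"),
                     file.path(outdir, "effects.json"))
      results$summary <- grid$summary
      results$effects <- eff
    } else if (name == "fig5_sweep") {
      sweep <- tradeoff_sweep(ml$model, family, vocab, n_seeds = n_seeds,
                              finetune = cfg$finetune_config,
                              space = cfg$meta_config$space, seed = seed)
      export_results(sweep, file.path(outdir, "sweep.csv"),
                     file.path(outdir, "sweep.json"))
      results$sweep <- sweep
    }
  }

  manifest <- list(preset = name, scale = scale, seed = seed,
                   n_seeds = n_seeds, family = family,
                   package_version = as.character(utils::packageVersion("iclsim")),
                   outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

write_trajectories <- function(trajs, outdir) {
  all <- do.call(rbind, lapply(names(trajs), function(nm) {
    d <- trajs[[nm]]
    d$run <- nm
    d
  }))
  utils::write.csv(all, file.path(outdir, "trajectories.csv"),
                   row.names = FALSE)
}

# minutes-scale structural self-check used by the `smoke` preset
smoke_check <- function(seed = 1L) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, pass = ok)
  for (cond in c("rule_like", "rotated")) {
    t <- sample_category_task(condition = cond, seed = seed)
    add(paste0("category_", cond, "_balance"),
        all(table(t$items$label) == 32) &&
          all(table(t$items$label[t$study]) == 16))
  }
  g <- sample_grid_task("rule_like", seed = seed)
  cur <- make_grid_curriculum(g, "blocked", seed = seed)
  add("grid_9_study_16_test",
      length(cur$order) == 9 && length(cur$test) == 16)
  ok_oracle <- all(vapply(cur$test, function(i) {
    ans <- compositional_answer(g$locations[cur$order, ],
                                g$locations$color[i], g$locations$animal[i])
    all(ans == c(g$locations$x[i], g$locations$y[i]))
  }, logical(1)))
  add("compositional_oracle_exhaustive", ok_oracle)
  vb <- build_vocab("compositional")
  mc <- model_config("compositional", "desk", n_layers = 1L,
                     hidden_size = 16L, dropout = 0)
  m <- init_model(mc, seed = seed)
  eps <- lapply(1:25, function(i) encode_episode(g, cur, i, vb))
  pr <- model_forward(m, eps[1:4], vb)
  add("forward_distributions_normalized",
      all(abs(apply(pr, c(1, 3), sum) - 1) < 1e-6))
  do.call(rbind, checks)
}
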