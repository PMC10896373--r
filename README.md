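# iclsim

Humans sometimes learn like rule-followers — a few examples suffice, and
blocking related trials together helps — and sometimes like slow
trial-and-error learners, where randomly interleaving trials helps and what
is learned is retained longer. `iclsim` is a simulation framework for the
hypothesis that both profiles can live inside one neural network: an
attention-based sequence model learns *in context* (ICL) through its
forward pass after being metalearned on a distribution of tasks, while
ordinary gradient descent provides *in-weight* learning (IWL). Because
weight updates are driven by errors, successful ICL suppresses IWL; when
ICL fails, IWL takes over — and with it come catastrophic forgetting under
blocked curricula and better context-free retention.

The package is aimed at computational cognitive scientists who want to run
the full simulation loop on a laptop: task generators, token encodings, a
compact decoder-only transformer (forward and backward passes are
hand-written in RcppArmadillo — no deep-learning framework is required),
metalearning and task-specific training, frozen-weight few-shot
evaluation, attention-ablation sweeps, retention tests, and the
curriculum-by-rotation statistics.

## The two task families

* **Category learning** — two feature dimensions with 8 discrete values
  (64 items), a balanced binary boundary that is either *rule-like* (one
  dimension decides: value ≤ 4 vs > 4) or *rotated* (decided by the sum of
  both values), 32 study items, 32 held out.
* **Compositional grid** — 5 colors × 5 animals on a 5×5 coordinate grid;
  in the rule-like condition color determines one coordinate and animal
  the other, so unseen color–animal pairs are answerable by composition.
  Nine study cues (one full row plus one full column), 16 test cues, and
  an optional 45° rotation `(u, v) = (x − y + 4, x + y)` that destroys the
  per-feature rule.

Study sets are presented *blocked* or *interleaved*, giving the 2×2
curriculum × structure design whose interaction is the central phenomenon.

## Worked example

Sample a compositional task, metalearn at desk scale, and inspect few-shot
generalization (desk scale runs in minutes on one CPU; it sits early in the
emergence of ICL — see the methods vignette for exactly what desk scale
does and does not establish):

```r
library(iclsim)

g   <- sample_grid_task("rule_like", seed = 12)
cur <- make_grid_curriculum(g, "interleaved", seed = 12)
head(render_grid_curriculum(g, cur), 3)
#> [1] "purple alligator -> (1, 1)" "purple bear -> (2, 1)"
#> [3] "green alligator -> (1, 2)"

# the symbolic oracle composes per-feature mappings for an unseen cue
i <- cur$test[1]
compositional_answer(g$locations[cur$order, ],
                     g$locations$color[i], g$locations$animal[i])
#> x y
#> 0 0

# from-scratch in-weight learning memorizes the 9 study cues but cannot
# compose: held-out accuracy stays at zero
m  <- init_model(model_config("compositional", "desk"), seed = 2)
vb <- build_vocab("compositional")
ft <- finetune_task(m, g, cur,
                    finetune_config("compositional", "desk",
                                    eval_every = 100),
                    vb, seed = 7)
subset(ft$trajectory, step == 300 & metric %in% c("acc_study", "acc_heldout"))
#>  step block trained_group      metric value
#>   300    30           row   acc_study     1
#>   300    30           row acc_heldout     0
```

The numbers above are what the calls print: in-weight learning reaches
ceiling on the studied cues and exactly zero on the 16 compositional test
cues — the generalization failure that metalearned in-context learning
repairs (`metalearn()`, then `few_shot_eval()`), and the starting point of
the flexibility–retention tradeoff measured by `tradeoff_sweep()`.

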