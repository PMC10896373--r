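---
title: "Methods: simulating the interplay of in-context and in-weight learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the interplay of in-context and in-weight learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`iclsim` studies a single sequence model that can learn in two
qualitatively different ways. *In-weight learning* (IWL) is ordinary
gradient descent: errors are backpropagated and change parameters.
*In-context learning* (ICL) happens inside a single forward pass: the model
reads a handful of study examples supplied in its input and answers a query
about a novel task without any parameter change. ICL is not built in; it
emerges when the network is *metalearned* — trained across a distribution
of related tasks so that solving a new task from its in-context examples
becomes the thing the weights encode.

The package implements the full loop around this idea for two task
families used in human curriculum-learning experiments:

* **Category learning.** Stimuli vary on two discrete feature dimensions
  with 8 values each (64 items). A balanced boundary assigns 32 items to
  each of two labels. In the *rule-like* condition a single dimension
  determines the label (value ≤ 4 vs > 4); in the *rotated*
  (information-integration) condition the label depends on the sum of the
  two values, so no single dimension suffices. 16 items per category are
  studied; 32 items are held out.
* **Compositional grid.** Five colors and five animals index a 5×5
  coordinate grid; in the rule-like condition one feature determines x and
  the other y, so the location of an unseen color–animal pair can be
  *composed* from per-feature mappings. Nine study cues (one full row plus
  one full column) are presented; the remaining 16 cues test compositional
  generalization. The rotated condition maps the grid through
  `(u, v) = (x − y + 4, x + y)` — a 45° rotation with √2 scaling chosen so
  all coordinates stay integers — after which no per-feature rule exists.

Study sets are presented either *blocked* (one category / one grid line in
full before the other) or *interleaved* (uniformly shuffled). Crossing
curriculum with rotation gives the 2×2 design whose interaction is the
headline phenomenon: a blocking advantage where rule-like structure is
available to ICL, and an interleaving advantage where failed ICL forces
error-driven IWL, which suffers catastrophic forgetting under blocking.

## Architecture and training

The network is a decoder-only transformer: a learnable token-embedding
dictionary shared with the output readout (weight tying), pre-layernorm
residual blocks, multi-head causal self-attention with per-head learnable
relative-distance biases, and a ReLU feedforward of width twice the hidden
size. Three choices here were made empirically, because the obvious
defaults simply never leave the loss plateau at small scale: (i)
*relative* rather than absolute positional information, so that a
retrieval circuit learned at context positions transfers to the query
position (half the heads start with a bias toward a specific short
offset, all trainable); (ii) tied embeddings, which make copy-a-context-
token circuits cheap to express; (iii) Xavier-style 1/sqrt(fan-in) weight
initialization -- with the common 0.02-everywhere initialization even a
pure key-value induction control task fails to form a retrieval circuit
within hundreds of optimizer steps, while with fan-in scaling it forms
reliably. An absolute-position variant remains available
(`model_config(positional = "learned")`). Reference (full-scale) configurations are 4 layers / 8
heads / hidden 64 / no dropout for the category family and 12 layers / 8
heads / hidden 64 / dropout 0.1 for the compositional family. Episodes are
fixed-width token sequences: each category study example is a (value,
value, label) triple and each compositional one a (color, animal, x, y)
quadruple; there are no separators (fixed-width runs keep positions
decodable) and a single query-marker token precedes the query. The loss is
cross-entropy on the answer tokens only, with teacher forcing during
training; evaluation is exact match under greedy decoding. Because no deep
learning framework is available to R in this environment, the forward and
backward passes are written directly in RcppArmadillo; the analytic
gradients are validated against central finite differences in the test
suite (relative error ~1e-6 across every parameter class).

Metalearning follows the reference recipe: tasks are sampled fresh
(12,000 for training, 100 validation, 10 test at full scale), all
rule-like and blocked by default; each training episode presents one task's
study context plus one query drawn uniformly from all items (study and
held-out queries equally likely — the `query_policy`); Adam with batch 256,
learning rate 1e-4 (category, 20 epochs) or 1e-3 (compositional, 500
epochs); the best-validation checkpoint is kept. The loss supervises the
answer tokens of the query only. Two denser supervision schemes —
additionally supervising the answer tokens inside the context, and full
next-token prediction over the whole episode — were evaluated and
rejected: both teach shortcut circuits (copy the running shared
coordinate, or match the immediately preceding token) that fit the context
positions while actively competing with the query-answering retrieval
circuit; with query-only loss the retrieval circuit forms, with either
dense scheme it does not. The option survives as
`meta_train_config(context_supervision = TRUE)`.

Task-specific training ("finetuning") gives feedback only on study-example
queries. In the blocked schedule the model takes `N` Adam steps on queries
from one stimulus group then `N` on the other, alternating (`N = 10`, 10
alternations by default); interleaved draws mixed batches. The context
shown in the input follows the same curriculum condition by default;
incongruent context/gradient combinations are available via
`gradient_curriculum`. After every step the trajectory records frozen-
weight exact-match accuracy per group and on held-out items, which is where
catastrophic forgetting is visible as the collapse of the first group's
accuracy during the second block.

## Ablation and retention

Working-memory load is modelled by inhibiting attention to each in-context
study example with probability `p_a`: a dropped example's tokens are
removed from the attention targets at every layer and head (sampled once
per episode per evaluation). Retention is probed by querying study items
*without* context: the query keeps its trained position, and the whole
context span is replaced by pad tokens that are also masked out as
attention keys, so nothing can be read out of the context and any correct
answer must come from the weights. The flexibility–retention tradeoff
(`tradeoff_sweep()`) then measures, per `p_a` level: few-shot accuracy of
the metalearned model, steps to a 0.9 study-accuracy criterion,
cumulative training loss, and retention accuracy.

## Desk scale: what it is and why

The reference configuration needs hours of CPU time. Most questions the
package answers are *qualitative sign patterns* (blocked minus interleaved
accuracy positive here, negative there; monotone trends along the ablation
grid), and those are checked at a reduced "desk" scale designed to run in
minutes on one CPU:

* model: 2 layers, 8 heads, dropout 0 (at this size dropout only delays
  the emergence of ICL); hidden 32 for the category family and hidden 64
  for the compositional family — at hidden 32 the compositional retrieval
  circuit does not leave its loss plateau within any tested budget;
* metalearning: 2,000 tasks, batch 256. Small transformers acquire
  in-context retrieval through a fairly abrupt phase transition whose
  onset varies considerably across seeds; with only tens of gradient
  steps the model learns nothing but the marginal token distribution
  (validation accuracy pinned at 1/25 while the loss converges to the
  marginal entropy). The desk epoch count for the compositional family
  (240, about 1,900 Adam steps) is sized near the typical onset, so a
  desk-scale metalearner may sit anywhere from the start of the
  transition to well into it depending on the seed — the suite treats the
  resulting criteria accordingly;
* the category desk distribution samples its two dimensions from a pool of
  30 rather than 200, so each (dimension, value) embedding receives enough
  updates within the desk budget. Full scale keeps the 200-dimension pool;
* finetuning at desk scale uses learning rates 5e-3 (category) and 3e-3
  (compositional) instead of 1e-5 / 1e-4, the largest rates at which
  memorization is stable, so from-scratch IWL converges within ~300 steps.

What a green desk-scale test does establish: the catastrophic-forgetting
signature and interleaving advantage of from-scratch IWL in the rotated
conditions, the failure of IWL to generalize compositionally, the chance
floors, the oracle equivalences, and the statistics machinery. What desk
scale demonstrably does *not* establish (and the corresponding acceptance
checks are expected to stay red with an analysis in the project ledger):
the reference-scale few-shot accuracies, the from-scratch interleaving
advantage in *rule-like* conditions — at desk learning rates a small
network extracts the one-dimensional rule from a single block within tens
of steps, so blocked training recovers instead of forgetting — and any
criterion that requires a fully emerged in-context learner within the test
harness budget. The full-scale presets (`run_preset(..., scale = "full")`)
exist for those.

## Numerical and design choices

* Feature values are indexed 1..8 so the printed midpoint rule ("A if
  length ≤ 4") is literal; the midpoint is the only balanced cut, and
  which side carries which label is randomized per task.
* The discrete 45° category boundary uses the anti-diagonal sum `v1 + v2`
  against 9; the eight diagonal items are split 4/4 by parity of `v1`.
  This is the minimal balanced discrete analogue of a rotated boundary;
  the tie-break is a pluggable field of the boundary object.
* The grid row/column intersection cue is presented once, inside the first
  block (9 presentations of 9 unique cues).
* Blocked category batches use the current group's 16 study queries once
  (`blocked_batch = "group"`); the alternative reading of the stated batch
  size 32 (`"repeat"`) is available as a switch.
* Steps-to-criterion uses a fixed 0.9 study-accuracy threshold.
* The curriculum × rotation statistics use a two-way between-run ANOVA
  plus a label-permutation cross-check of the interaction F statistic
  (the two agree within a factor of 2 for p in [0.001, 0.5] on planted
  designs, which is tested).
* Retention is evaluated immediately after finetuning; the human "delay"
  is operationalized purely as removal of context.
* All sampling is a pure function of explicit integer seeds; derived
  sub-seeds stay below 2^31.

## Limitations

The synthetic generators emulate the token-level structure of the tasks,
not their perceptual front end: there is no stimulus noise, no continuous
feature dimensions, and no response-interface model. The desk scale trades
the reference effect sizes for speed, and the "noise" ablation mode is a
config hook only. LLM evaluation of the compositional task is out of
scope; `render_grid_curriculum()` produces prompt-ready text for such a
harness but no API client is included.
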