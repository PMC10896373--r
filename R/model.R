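#' Transformer configuration
#'
#' Reference settings per task family follow the simulation defaults:
#' category -- 4 layers, 8 heads, hidden size 64, no dropout; compositional
#' -- 12 layers, 8 heads, hidden size 64, dropout 0.1. The feedforward
#' width is always twice the hidden size. `scale = "desk"` substitutes the
#' reduced architecture (2 layers, hidden 32) used by the fast qualitative
#' property suite.
#'
#' @param family `"category"` or `"compositional"`.
#' @param scale `"full"` or `"desk"`.
#' @param n_layers,n_heads,hidden_size,dropout,max_sequence_length optional
#'   overrides of the family defaults.
#' @param d_v vocabulary size; defaults to the family vocabulary's size.
#' @param tie_embeddings share the token-embedding dictionary with the
#'   output projection (reading a token out costs what writing it in does;
#'   this is what makes copy-from-context circuits easy to form).
#' @param positional `"relative"` (default): per-head learnable
#'   relative-distance attention biases, translation-invariant, which is
#'   what lets in-context retrieval circuits generalize across positions;
#'   `"learned"`: absolute learned position embeddings.
#' @param space feature space used to size the category vocabulary.
#' @return object of class `model_config`.
#' @export
model_config <- function(family = c("category", "compositional"),
                         scale = c("full", "desk"),
                         n_layers = NULL, n_heads = 8L, hidden_size = NULL,
                         dropout = NULL, d_v = NULL,
                         max_sequence_length = NULL, tie_embeddings = TRUE,
                         positional = c("relative", "learned"),
                         space = NULL) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  positional <- match.arg(positional)
  if (is.null(space))
    space <- if (family == "category" && scale == "desk")
      feature_space(30L) else feature_space()
  defaults <- if (family == "category") {
    list(n_layers = 4L, hidden_size = 64L, dropout = 0,
         max_sequence_length = 128L)
  } else {
    list(n_layers = 12L, hidden_size = 64L, dropout = 0.1,
         max_sequence_length = 64L)
  }
  if (scale == "desk") {
    defaults$n_layers <- 2L
    # the compositional retrieval circuit does not leave its loss plateau
    # at hidden 32 within any desk budget; 64 is the smallest size that does
    defaults$hidden_size <- if (family == "compositional") 64L else 32L
    defaults$dropout <- 0 # dropout only delays ICL emergence at this size
  }
  n_layers <- as.integer(n_layers %||% defaults$n_layers)
  hidden_size <- as.integer(hidden_size %||% defaults$hidden_size)
  dropout <- dropout %||% defaults$dropout
  max_sequence_length <- as.integer(max_sequence_length %||%
                                      defaults$max_sequence_length)
  if (is.null(d_v)) d_v <- build_vocab(family, space)$n
  n_heads <- as.integer(n_heads)
  if (hidden_size %% n_heads != 0L)
    stop("config error: n_heads must divide hidden_size")
  if (dropout < 0 || dropout >= 1) stop("config error: dropout in [0, 1)")
  structure(list(family = family, scale = scale, n_layers = n_layers,
                 n_heads = n_heads, hidden_size = hidden_size,
                 ffn_size = 2L * hidden_size, dropout = dropout,
                 d_v = as.integer(d_v),
                 max_sequence_length = max_sequence_length,
                 tie_embeddings = isTRUE(tie_embeddings),
                 positional = positional),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s/%s: %d layers, %d heads, hidden %d, ffn %d, dropout %g, d_v %d\n",
              x$family, x$scale, x$n_layers, x$n_heads, x$hidden_size,
              x$ffn_size, x$dropout, x$d_v))
  invisible(x)
}

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# weight matrices use 1/sqrt(fan_in) scaling; embeddings stay at 0.02 so
# the initial logits (tied readout) are near-uniform
init_w <- function(nr, nc) init_mat(nr, nc, sd = 1 / sqrt(nr))

#' Initialize a model
#'
#' Learnable token embeddings (a dictionary of random vectors), learned
#' positional embeddings, and pre-layernorm attention/feedforward blocks,
#' all drawn N(0, 0.02^2); layernorm gains start at 1. Deterministic given
#' `(config, seed)`.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return object of class `icl_model`: `config` plus the parameter list.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  h <- config$hidden_size
  f <- config$ffn_size
  withr::with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      ly <- list(Wq = init_w(h, h), bq = numeric(h),
                 Wk = init_w(h, h), bk = numeric(h),
                 Wv = init_w(h, h), bv = numeric(h),
                 Wo = init_w(h, h), bo = numeric(h),
                 g1 = rep(1, h), b1 = numeric(h),
                 g2 = rep(1, h), b2 = numeric(h),
                 W1 = init_w(h, f), c1 = numeric(f),
                 W2 = init_w(f, h), c2 = numeric(h))
      if (config$positional == "relative") {
        # offset priors: head k starts biased toward distance k (half the
        # heads), the rest start neutral (content-matching heads); all
        # trainable
        rb <- matrix(0, config$max_sequence_length, config$n_heads)
        for (hd in seq_len(config$n_heads %/% 2L))
          if (hd + 1L <= nrow(rb)) rb[hd + 1L, hd] <- 2
        ly$rb <- rb
      }
      ly
    })
    params <- list(emb = init_mat(config$d_v, h),
                   gf = rep(1, h), bf = numeric(h),
                   bu = numeric(config$d_v), layers = layers)
    if (config$positional == "learned")
      params$pos <- init_mat(config$max_sequence_length, h)
    if (!config$tie_embeddings)
      params$Wu <- init_w(h, config$d_v)
    structure(list(config = config, params = params, seed = seed),
              class = "icl_model")
  })
}

#' @export
print.icl_model <- function(x, ...) {
  cat(sprintf("<icl_model> %s (%d parameters)\n", x$config$family,
              param_count(x)))
  print(x$config)
  invisible(x)
}

#' Number of learnable parameters
#' @param model an [init_model()] result.
#' @export
param_count <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(model$params)
}

#' Attention-ablation specification
#'
#' With probability `p_a`, attention to each in-context study example is
#' inhibited: all of the example's tokens are removed from the attention
#' targets at every layer and head. Dropping is sampled independently per
#' example, once per episode per evaluation.
#'
#' @param p_a probability in \[0, 1\].
#' @param mode only `"drop"` is implemented; `"noise"` is reserved as a
#'   config hook.
#' @param seed optional integer seed for the drop sampling.
#' @export
ablation_spec <- function(p_a, mode = c("drop", "noise"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "noise") stop("noise ablation is a config hook only; use mode = 'drop'")
  if (!is.numeric(p_a) || length(p_a) != 1L || is.na(p_a) ||
      p_a < 0 || p_a > 1)
    stop("p_a must be a single probability in [0, 1]")
  structure(list(p_a = p_a, mode = mode, seed = seed),
            class = "ablation_spec")
}

batch_with_ablation <- function(episodes, vocab, ablation) {
  if (!is.null(ablation) && !is.null(ablation$seed))
    withr::with_seed(ablation$seed, episode_batch(episodes, vocab, ablation))
  else episode_batch(episodes, vocab, ablation)
}

#' Forward pass: next-token distributions at the answer positions
#'
#' Evaluation-mode forward (no dropout, no parameter change). Returns the
#' softmax-normalized distributions over the vocabulary for each target
#' position of each episode.
#'
#' @param model an [init_model()] result.
#' @param episodes list of episodes (one geometry).
#' @param vocab the family vocabulary.
#' @param ablation optional [ablation_spec()].
#' @return array `[n_targets, d_v, B]` of probabilities.
#' @export
model_forward <- function(model, episodes, vocab, ablation = NULL) {
  bt <- batch_with_ablation(episodes, vocab, ablation)
  out <- .tf_batch(model$params, unclass(model$config), bt$tokens,
                   bt$keymask, bt$target_pos, NULL, FALSE, FALSE, 0L)
  lg <- out$logits
  for (b in seq_len(dim(lg)[3]))
    for (k in seq_len(dim(lg)[1])) {
      row <- lg[k, , b]
      row <- exp(row - max(row))
      lg[k, , b] <- row / sum(row)
    }
  lg
}

#' Full per-position logits (diagnostic)
#' @inheritParams model_forward
#' @return list of `T x d_v` logit matrices, one per episode.
#' @export
model_full_logits <- function(model, episodes, vocab, ablation = NULL) {
  bt <- batch_with_ablation(episodes, vocab, ablation)
  .tf_full_logits(model$params, unclass(model$config), bt$tokens, bt$keymask)
}

#' Greedy decoding of the answer tokens
#'
#' Emits the argmax token at each answer position, feeding predictions back
#' autoregressively for multi-token answers. Deterministic given the model
#' state (ablation masks are sampled from `ablation$seed` when supplied).
#'
#' @inheritParams model_forward
#' @return integer matrix `B x n_targets` of predicted token ids (0-based).
#' @export
greedy_decode <- function(model, episodes, vocab, ablation = NULL) {
  bt <- batch_with_ablation(episodes, vocab, ablation)
  n_t <- ncol(bt$targets)
  B <- nrow(bt$tokens)
  preds <- matrix(NA_integer_, B, n_t)
  tokens <- bt$tokens
  for (k in seq_len(n_t)) {
    pos <- bt$target_pos[k]
    out <- .tf_batch(model$params, unclass(model$config), tokens,
                     bt$keymask, pos, NULL, FALSE, FALSE, 0L)
    pred <- apply(out$logits[1, , , drop = FALSE], 3, which.max) - 1L
    preds[, k] <- pred
    if (k < n_t) tokens[, pos + 2L] <- pred # overwrite teacher token
  }
  preds
}

#' Save / load a model checkpoint
#'
#' Parameters and config are stored in an RDS container with a JSON sidecar
#' describing the architecture, so checkpoints are self-describing.
#'
#' @param model an `icl_model`.
#' @param path file path (`.rds`); the sidecar is `path` + `.json`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

params_flatten <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        name <- if (!is.null(names(x))) names(x)[nm] else as.character(nm)
        walk(x[[nm]], paste0(prefix, ".", name))
      }
    } else out[[prefix]] <<- x
  }
  walk(p, "p")
  out
}

params_hash <- function(model) {
  flat <- params_flatten(model$params)
  sum(vapply(flat, function(m) sum(as.numeric(m)), numeric(1)))
}
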