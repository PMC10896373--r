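#' Build the token vocabulary for a task family
#'
#' Token ids are dense, 0-based, and deterministic given the family and
#' feature space. The category vocabulary contains one token per
#' (pool dimension, value) pair -- so held-out metalearning tasks introduce
#' no new tokens -- plus the two label tokens and structural tokens. The
#' compositional vocabulary contains the color and animal words, coordinate
#' tokens covering both the unrotated (0..4) and rotated (0..8) ranges, and
#' structural tokens. Chance exact-match accuracy for an unconstrained
#' predictor is `1 / vocab$n`.
#'
#' @param family `"category"` or `"compositional"`.
#' @param space a [feature_space()] (category family only).
#' @return object of class `icl_vocab`: data frame `tokens` (`token`, `id`,
#'   `class`), size `n`, and the family layout used by the encoder.
#' @export
build_vocab <- function(family = c("category", "compositional"),
                        space = feature_space()) {
  family <- match.arg(family)
  if (family == "category") {
    nv <- space$values_per_dim
    feat <- paste0("d", rep(seq_len(space$pool_size), each = nv), ":",
                   rep(seq_len(nv), space$pool_size))
    tok <- c(feat, "A", "B", "<q>", "<pad>")
    cls <- c(rep("feature", length(feat)), "label", "label",
             "structural", "structural")
    layout <- list(run_length = 3L, n_study = 2L * nv^2 %/% 4L,
                   n_targets = 1L)
  } else {
    coords <- as.character(0:8)
    tok <- c(grid_colors, grid_animals, coords, "<q>", "<pad>")
    cls <- c(rep("color", 5L), rep("animal", 5L), rep("coordinate", 9L),
             "structural", "structural")
    layout <- list(run_length = 4L, n_study = 9L, n_targets = 2L)
    space <- NULL
  }
  tab <- data.frame(token = tok, id = seq_along(tok) - 1L, class = cls,
                    stringsAsFactors = FALSE)
  structure(list(tokens = tab, n = nrow(tab), family = family,
                 space = space, layout = layout), class = "icl_vocab")
}

#' @export
print.icl_vocab <- function(x, ...) {
  cat(sprintf("<icl_vocab> %s family, %d tokens\n", x$family, x$n))
  invisible(x)
}

token_id <- function(vocab, token) {
  id <- vocab$tokens$id[match(token, vocab$tokens$token)]
  if (anyNA(id)) stop("unknown token(s): ",
                      paste(token[is.na(id)], collapse = ", "))
  id
}

id_token <- function(vocab, id) {
  tok <- vocab$tokens$token[match(id, vocab$tokens$id)]
  if (anyNA(tok)) stop("unknown token id(s)")
  tok
}

cat_value_token <- function(dim, value) paste0("d", dim, ":", value)

#' Encode one query of a task as a model episode
#'
#' The context is the ordered study set of the curriculum: category study
#' examples are (value, value, label) triples, compositional ones are
#' (color, animal, x, y) quadruples, with no separators between examples.
#' A single query-marker token precedes the query cue; the answer tokens
#' (1 label, or 2 coordinates) are withheld as the target.
#'
#' @param task a `category_task` or `grid_task`.
#' @param curriculum the matching curriculum object.
#' @param query_index row index into the task's item table.
#' @param vocab the family vocabulary from [build_vocab()].
#' @return object of class `icl_episode` with 0-based token id vectors
#'   `context`, `query`, `target`, plus `group_id` and `split`.
#' @export
encode_episode <- function(task, curriculum, query_index, vocab) {
  if (inherits(task, "category_task")) {
    stopifnot(vocab$family == "category")
    it <- task$items
    enc_item <- function(i, with_label) {
      toks <- c(cat_value_token(task$dims[1], it$v1[i]),
                cat_value_token(task$dims[2], it$v2[i]))
      if (with_label) toks <- c(toks, it$label[i])
      token_id(vocab, toks)
    }
    context <- unlist(lapply(curriculum$order, enc_item, with_label = TRUE))
    query <- enc_item(query_index, with_label = FALSE)
    target <- token_id(vocab, it$label[query_index])
    group_id <- it$label[query_index]
    split <- if (query_index %in% task$study) "study" else "heldout"
  } else if (inherits(task, "grid_task")) {
    stopifnot(vocab$family == "compositional")
    loc <- task$locations
    enc_cue <- function(i, with_answer) {
      toks <- c(loc$color[i], loc$animal[i])
      if (with_answer) toks <- c(toks, as.character(loc$x[i]),
                                 as.character(loc$y[i]))
      token_id(vocab, toks)
    }
    context <- unlist(lapply(curriculum$order, enc_cue, with_answer = TRUE))
    query <- enc_cue(query_index, with_answer = FALSE)
    target <- token_id(vocab, as.character(c(loc$x[query_index],
                                             loc$y[query_index])))
    pos <- match(query_index, curriculum$order)
    group_id <- if (!is.na(pos)) curriculum$groups[pos] else "test"
    split <- if (query_index %in% curriculum$order) "study" else "heldout"
  } else stop("unsupported task type")
  structure(list(family = vocab$family, context = as.integer(context),
                 query = as.integer(query), target = as.integer(target),
                 n_context_full = length(context),
                 group_id = group_id, split = split,
                 query_index = query_index),
            class = "icl_episode")
}

#' Decode an episode back to tokens
#' @param episode an [encode_episode()] result.
#' @param vocab the matching vocabulary.
#' @return list of character vectors `context`, `query`, `target`.
#' @export
decode_episode <- function(episode, vocab) {
  list(context = id_token(vocab, episode$context),
       query = id_token(vocab, episode$query),
       target = id_token(vocab, episode$target))
}

#' Remove the study context from an episode
#'
#' The retention-test input: the query and target are unchanged, the context
#' is gone. The model evaluator keeps the query at its trained position by
#' substituting masked pad tokens for the missing context, so no contextual
#' information is available through attention (the key mask zeroes the whole
#' context span). Idempotent.
#'
#' @param episode an [encode_episode()] result.
#' @return the episode with empty `context` and `stripped = TRUE`.
#' @export
strip_context <- function(episode) {
  episode$context <- integer(0)
  episode$stripped <- TRUE
  episode
}

#' Assemble episodes into a model batch
#'
#' All episodes must share one geometry (same family, same context status).
#' The model input sequence is `context, <q>, query, target[1..k-1]` (the
#' trailing target token is never fed in); the loss/readout positions are
#' those whose next-token prediction is an answer token. Stripped episodes
#' are padded back to the full context width with `<pad>` tokens whose keys
#' are masked. With an ablation, each study example is dropped (all its
#' tokens masked as attention keys) independently with probability `p_a`,
#' sampled once per episode.
#'
#' @param episodes list of [encode_episode()] results.
#' @param vocab the family vocabulary.
#' @param ablation optional [ablation_spec()].
#' @return list: `tokens` (B x T, 0-based ids), `target_pos` (0-based),
#'   `targets` (B x n_t), `keymask` (B x T or NULL).
#' @export
episode_batch <- function(episodes, vocab, ablation = NULL) {
  stopifnot(length(episodes) > 0)
  qm <- token_id(vocab, "<q>")
  pad <- token_id(vocab, "<pad>")
  run <- vocab$layout$run_length
  n_t <- length(episodes[[1]]$target)
  nc <- episodes[[1]]$n_context_full
  seqs <- lapply(episodes, function(ep) {
    stopifnot(length(ep$target) == n_t, ep$n_context_full == nc)
    ctx <- ep$context
    if (length(ctx) == 0L && nc > 0L) ctx <- rep(pad, nc)
    c(ctx, qm, ep$query, ep$target[seq_len(n_t - 1L)])
  })
  T_len <- length(seqs[[1]])
  tokens <- do.call(rbind, seqs)
  storage.mode(tokens) <- "integer"
  # position whose output predicts target k: last input index + (k-1)
  q_end <- nc + 1L + length(episodes[[1]]$query) # 1-based index of last query token
  target_pos <- (q_end - 1L) + seq_len(n_t) - 1L # 0-based
  targets <- do.call(rbind, lapply(episodes, function(ep) ep$target))
  storage.mode(targets) <- "integer"

  keymask <- NULL
  stripped <- vapply(episodes, function(ep) isTRUE(ep$stripped), logical(1))
  p_a <- if (!is.null(ablation)) ablation$p_a else 0
  if (any(stripped) || p_a > 0) {
    keymask <- matrix(1, nrow = length(episodes), ncol = T_len)
    n_ex <- nc %/% run
    for (b in seq_along(episodes)) {
      if (stripped[b]) {
        if (nc > 0L) keymask[b, seq_len(nc)] <- 0
      } else if (p_a > 0) {
        drop <- stats::runif(n_ex) < p_a
        for (e in which(drop))
          keymask[b, ((e - 1L) * run + 1L):(e * run)] <- 0
      }
    }
  }
  list(tokens = tokens, target_pos = as.integer(target_pos),
       targets = targets, keymask = keymask)
}
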