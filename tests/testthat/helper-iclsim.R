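# Shared fixtures. Everything is generated in code; the expensive
# metalearned checkpoints are built once per test session and memoised.

tiny_config <- function(family = "compositional", n_layers = 1L,
                        hidden_size = 16L, n_heads = 4L, dropout = 0) {
  model_config(family, "desk", n_layers = n_layers,
               hidden_size = hidden_size, n_heads = n_heads,
               dropout = dropout)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    message("building fixture: ", name)
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Desk-scale metalearned checkpoints shared by the acceptance criteria.
# Scale notes: the task counts/epochs are the desk preset; see the methods
# vignette for the rationale.
meta_category <- function() fixture("meta_category", function() {
  metalearn(model_config("category", "desk"),
            meta_train_config("category", "desk"), seed = 2024L)
})

meta_compositional <- function() fixture("meta_compositional", function() {
  metalearn(model_config("compositional", "desk"),
            meta_train_config("compositional", "desk"), seed = 2024L)
})

vocab_category <- function() fixture("vocab_category",
                                     function() build_vocab("category"))
vocab_compositional <- function() fixture("vocab_compositional",
                                          function() build_vocab("compositional"))

expect_setequal_int <- function(a, b) expect_setequal(as.integer(a),
                                                      as.integer(b))

sample_family_task_test <- function(family, rotation, seed) {
  if (family == "category")
    sample_category_task(condition = rotation, seed = seed)
  else sample_grid_task(rotation, seed = seed)
}
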