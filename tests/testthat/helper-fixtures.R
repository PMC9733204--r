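# Shared fixtures: tiny model configurations and cached toy corpora so the
# expensive pieces are built once per test run.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_size = 8L, layers = 1L, stack_width = 2L, stack_depth = 3L,
         latent_dim = 4L, embedding_dim = 6L, max_len = 40L, batch_size = 4L,
         learning_rate = 5e-3),
    list(...))
  do.call(model_config, args)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_size = 32L, layers = 1L, stack_width = 8L, stack_depth = 4L,
         latent_dim = 8L, embedding_dim = 16L, max_len = 60L,
         batch_size = 16L, learning_rate = 5e-3),
    list(...))
  do.call(model_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_corpus_100 <- function() cached("corpus100", generate_toy_corpus(100, seed = 7))

# a small pretrained model shared by generation/episode tests
tiny_trained <- function() {
  cached("tiny_trained", {
    corp <- generate_toy_corpus(40, seed = 11)
    pretrain(corp, tiny_config(), epochs = 2, seed = 1)
  })
}

ref_cond <- function() cached("ref_cond", compute_conditions("CCC(=O)Nc1ccccc1"))

# stub oracles with fixed outputs, for exact reward arithmetic
const_oracles <- function(affinity, rascore) {
  list(affinity = function(smiles, protein) affinity[[protein]],
       synth = function(smiles) rascore)
}

random_onehot_trace <- function(len, width) {
  lapply(seq_len(len), function(i) {
    op <- sample(c("push", "pop", "noop"), 1L)
    if (op == "push") list(op = op, value = round(stats::runif(width), 3))
    else list(op = op)
  })
}

# continuous stack update driven by a discrete trace (one-hot actions)
apply_onehot_continuous <- function(initial, trace) {
  s <- initial
  for (step in trace) {
    a <- c(push = 0, pop = 0, noop = 0)
    a[step$op] <- 1
    v <- if (step$op == "push") step$value else numeric(ncol(initial))
    s <- update_stack(s, a, v)
  }
  s
}
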