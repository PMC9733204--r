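#' Model configuration
#'
#' Returns the architecture and training hyper-parameters for a stack-CVAE
#' model. Defaults follow the reference architecture: a 3-layer
#' stack-augmented recurrent encoder with 512 hidden nodes, stack width 50
#' and depth 10, and a 3-layer GRU decoder with 512 hidden nodes. Small
#' models for tests and examples are obtained by overriding the sizes.
#'
#' @param hidden_size Hidden units per recurrent layer (m).
#' @param layers Number of recurrent layers in encoder and decoder.
#' @param stack_width Width k of one stack element.
#' @param stack_depth Depth p of the stack.
#' @param latent_dim Latent-space dimension.
#' @param embedding_dim Token-embedding dimension.
#' @param max_len Maximum generation length (tokens) before truncation.
#' @param use_stack If `FALSE` the encoder runs the same recurrent cell with
#'   the stack disabled (the plain-recurrent CVAE ablation).
#' @param learning_rate Adam learning rate for pretraining.
#' @param batch_size Sequences per gradient step.
#' @param kl_weight Weight on the KL term of the objective (default 1, no
#'   annealing).
#' @param seed Integer seed recorded in the config.
#' @return A list of class `stack_cvae_config`.
#' @export
model_config <- function(hidden_size = 512L, layers = 3L, stack_width = 50L,
                         stack_depth = 10L, latent_dim = 128L,
                         embedding_dim = 128L, max_len = 100L,
                         use_stack = TRUE, learning_rate = 1e-3,
                         batch_size = 64L, kl_weight = 1, seed = 1L) {
  cfg <- list(hidden_size = as.integer(hidden_size), layers = as.integer(layers),
              stack_width = as.integer(stack_width),
              stack_depth = as.integer(stack_depth),
              latent_dim = as.integer(latent_dim),
              embedding_dim = as.integer(embedding_dim),
              max_len = as.integer(max_len), use_stack = isTRUE(use_stack),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              kl_weight = kl_weight, seed = as.integer(seed))
  stopifnot(cfg$hidden_size > 0, cfg$layers > 0, cfg$stack_width > 0,
            cfg$stack_depth > 0, cfg$latent_dim > 0, cfg$embedding_dim > 0,
            cfg$max_len > 0)
  structure(cfg, class = "stack_cvae_config")
}

#' Build an untrained stack-CVAE model
#'
#' @param vocab A `smiles_vocabulary`.
#' @param config A `stack_cvae_config`.
#' @param cond_stats Condition-scaling statistics from [condition_stats()];
#'   `NULL` gives identity scaling.
#' @param seed Seed for weight initialization.
#' @param zero_init If `TRUE`, all weights start at zero (used by contract
#'   tests on closed forms).
#' @return A list of class `stack_cvae` holding the vocabulary, config,
#'   scaling statistics, and all weight matrices.
#' @export
build_model <- function(vocab, config, cond_stats = NULL, seed = config$seed,
                        zero_init = FALSE) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  V <- length(vocab$tokens)
  m <- config$hidden_size; dz <- config$latent_dim; de <- config$embedding_dim
  k <- config$stack_width; p <- config$stack_depth; L <- config$layers
  sc <- if (zero_init) 0 else 0.1
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -sc, sc), nr, nc)
  enc <- vector("list", L)
  dec <- vector("list", L)
  for (l in seq_len(L)) {
    enc_in <- if (l == 1L) de + 3L else m
    dec_in <- if (l == 1L) de + dz + 3L else m
    enc[[l]] <- stack_cell_params(m, k, enc_in, init_scale = sc)
    dec[[l]] <- gru_params(m, dec_in, init_scale = sc)
  }
  if (is.null(cond_stats)) {
    cond_stats <- list(mean = c(mol_weight = 0, logp = 0, tpsa = 0),
                       sd = c(mol_weight = 1, logp = 1, tpsa = 1))
  }
  structure(list(
    vocab = vocab, config = config, cond_stats = cond_stats,
    E = ru(de, V),
    enc = enc,
    W_mu = ru(dz, m), b_mu = numeric(dz),
    W_lv = ru(dz, m), b_lv = numeric(dz),
    dec = dec,
    W_out = ru(V, m), b_out = numeric(V)
  ), class = "stack_cvae")
}

#' @export
print.stack_cvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("stack-CVAE model: %d-layer %s encoder (m=%d), ",
                     "%d-layer GRU decoder, |vocab|=%d, d_z=%d\n"),
              cfg$layers, if (cfg$use_stack) "stack-RNN" else "RNN",
              cfg$hidden_size, cfg$layers, length(x$vocab$tokens),
              cfg$latent_dim))
  invisible(x)
}

.token_ids <- function(seq, vocab) {
  ids <- vocab$index[seq$tokens]
  if (anyNA(ids)) stop("token sequence contains tokens outside the vocabulary: ",
                       paste(seq$tokens[is.na(ids)], collapse = " "))
  as.integer(ids)
}

.scaled_cond <- function(model, cond) scale_conditions(cond, model$cond_stats)

# Encoder forward over the full delimited token sequence; keeps caches when
# requested (training).
.encode_forward <- function(model, ids, cond3, keep = FALSE) {
  cfg <- model$config
  L <- cfg$layers
  h <- replicate(L, numeric(cfg$hidden_size), simplify = FALSE)
  s <- if (cfg$use_stack) {
    replicate(L, matrix(0, cfg$stack_depth, cfg$stack_width), simplify = FALSE)
  } else replicate(L, NULL, simplify = FALSE)
  n <- length(ids)
  caches <- if (keep) vector("list", n) else NULL
  for (t in seq_len(n)) {
    x <- c(model$E[, ids[t]], cond3)
    layer_caches <- if (keep) vector("list", L) else NULL
    for (l in seq_len(L)) {
      cc <- .cell_forward(x, h[[l]], s[[l]], model$enc[[l]])
      h[[l]] <- cc$h
      s[l] <- list(cc$stack)  # NULL-safe assignment for the stack-less cell
      x <- cc$h
      if (keep) layer_caches[[l]] <- cc
    }
    if (keep) caches[[t]] <- layer_caches
  }
  list(h_final = h[[L]], caches = caches)
}

#' Encode a token sequence into posterior parameters
#'
#' Runs the stack-augmented encoder over the embedded tokens, each step's
#' input concatenated with the standardized condition vector, and maps the
#' final hidden state linearly to the Gaussian posterior parameters.
#'
#' @param seq A `token_sequence`.
#' @param cond Named condition vector from [compute_conditions()].
#' @param model A `stack_cvae` model.
#' @return List with `mean` and `log_variance` (numeric vectors of length
#'   `latent_dim`).
#' @export
encode <- function(seq, cond, model) {
  ids <- .token_ids(seq, model$vocab)
  cond3 <- .scaled_cond(model, cond)
  h <- .encode_forward(model, ids, cond3)$h_final
  list(mean = as.numeric(model$W_mu %*% h + model$b_mu),
       log_variance = as.numeric(model$W_lv %*% h + model$b_lv))
}

#' Draw a latent code by reparameterized sampling
#'
#' `z = mean + exp(log_variance / 2) * eps` with `eps` standard normal.
#'
#' @param post Posterior list from [encode()].
#' @param seed Optional integer seed (scoped to this call).
#' @return Numeric latent vector.
#' @export
sample_latent <- function(post, seed = NULL) {
  if (!is.null(seed)) {
    restore <- .Random.seed_guard(seed)
    on.exit(restore(), add = TRUE)
  }
  eps <- stats::rnorm(length(post$mean))
  as.numeric(post$mean + exp(post$log_variance / 2) * eps)
}

#' CVAE training objective
#'
#' Reconstruction is the summed token-wise cross entropy of the next-token
#' distributions against the target tokens (the sequence shifted by one);
#' the KL term is the closed-form Gaussian divergence
#' `0.5 * sum(mu^2 + exp(lv) - 1 - lv)` against the standard-normal prior.
#'
#' @param seq The delimited `token_sequence` being reconstructed.
#' @param post Posterior list (`mean`, `log_variance`).
#' @param step_dists List of next-token probability vectors, one per
#'   prediction step (`length(seq$tokens) - 1` of them).
#' @param vocab The `smiles_vocabulary` indexing the distributions.
#' @param kl_weight Weight on the KL term (default 1).
#' @return List with `total`, `reconstruction`, `kl`.
#' @export
cvae_loss <- function(seq, post, step_dists, vocab, kl_weight = 1) {
  ids <- .token_ids(seq, vocab)
  targets <- ids[-1L]
  if (length(step_dists) != length(targets)) {
    stop("got ", length(step_dists), " step distributions for ",
         length(targets), " target tokens")
  }
  rec <- 0
  for (t in seq_along(targets)) {
    p <- step_dists[[t]][targets[t]]
    rec <- rec - log(max(p, 1e-12))
  }
  mu <- post$mean; lv <- post$log_variance
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  list(total = rec + kl_weight * kl, reconstruction = rec, kl = kl)
}

.decoder_init <- function(model) {
  replicate(model$config$layers, numeric(model$config$hidden_size),
            simplify = FALSE)
}

# One decoder step; returns next-token distribution and updated state.
.decoder_step <- function(model, token_id, z, cond3, state, keep = FALSE) {
  x <- c(model$E[, token_id], z, cond3)
  L <- model$config$layers
  caches <- if (keep) vector("list", L) else NULL
  for (l in seq_len(L)) {
    cc <- gru_forward(x, state[[l]], model$dec[[l]])
    state[[l]] <- cc$h
    x <- cc$h
    if (keep) caches[[l]] <- cc
  }
  logits <- as.numeric(model$W_out %*% x + model$b_out)
  logits <- logits - max(logits)
  e <- exp(logits)
  list(probs = e / sum(e), state = state, caches = caches, h_top = x)
}

#' Next-token distribution of the decoder
#'
#' Teacher-forced single query: runs the decoder over `prev_tokens` (which
#' must start with `<`) and returns the probability distribution for the
#' next token. Mainly for inspection and tests.
#'
#' @param model A `stack_cvae` model.
#' @param prev_tokens Character vector of tokens consumed so far.
#' @param z Latent vector (length `latent_dim`).
#' @param cond Named condition vector.
#' @return Named numeric probability vector over the vocabulary.
#' @export
step_distribution <- function(model, prev_tokens, z, cond) {
  ids <- model$vocab$index[prev_tokens]
  if (anyNA(ids)) stop("unknown token in prev_tokens")
  cond3 <- .scaled_cond(model, cond)
  state <- .decoder_init(model)
  out <- NULL
  for (id in ids) {
    out <- .decoder_step(model, id, z, cond3, state)
    state <- out$state
  }
  stats::setNames(out$probs, model$vocab$tokens)
}

#' Generate a SMILES string from the decoder
#'
#' Autoregressive sampling: starting from the start token `<`, each next
#' token is sampled from the decoder's softmax distribution (with the latent
#' code and condition vector concatenated into every input step) until the
#' end token `>` appears or `max_len` tokens have been emitted.
#'
#' @param model A `stack_cvae` model.
#' @param cond Named condition vector (the reference molecule's descriptors).
#' @param z Latent vector, or `NULL` to sample `z ~ N(0, I)`.
#' @param max_len Maximum number of emitted tokens (default from config).
#' @param seed Optional integer seed (scoped to this call).
#' @return The generated interior SMILES string, with attribute `truncated`
#'   set to `TRUE` when generation hit `max_len` without emitting `>`.
#' @export
generate_smiles <- function(model, cond, z = NULL, max_len = NULL, seed = NULL) {
  if (!is.null(seed)) {
    restore <- .Random.seed_guard(seed)
    on.exit(restore(), add = TRUE)
  }
  if (is.null(max_len)) max_len <- model$config$max_len
  if (is.null(z)) z <- stats::rnorm(model$config$latent_dim)
  cond3 <- .scaled_cond(model, cond)
  ep <- .sample_tokens(model, z, cond3, max_len)
  out <- if (length(ep$interior_ids)) {
    paste(model$vocab$tokens[ep$interior_ids], collapse = "")
  } else ""
  attr(out, "truncated") <- ep$truncated
  out
}

# Core sampling loop shared by generation and RL episodes. Records the
# probability of each chosen token and (optionally) the GRU caches needed
# for the policy-gradient backward pass.
.sample_tokens <- function(model, z, cond3, max_len, keep = FALSE) {
  vocab <- model$vocab
  start_id <- vocab$index[[START_TOKEN]]
  end_id <- vocab$index[[END_TOKEN]]
  pad_id <- vocab$index[[PAD_TOKEN]]
  state <- .decoder_init(model)
  cur <- start_id
  chosen <- integer(0)
  probs <- numeric(0)
  step_caches <- list()
  dists <- list()
  truncated <- TRUE
  for (t in seq_len(max_len)) {
    out <- .decoder_step(model, cur, z, cond3, state, keep = keep)
    state <- out$state
    p <- out$probs
    p[pad_id] <- 0            # padding is never a legal emission
    p <- p / sum(p)
    nxt <- sample.int(length(p), 1L, prob = p)
    chosen <- c(chosen, nxt)
    probs <- c(probs, p[nxt])
    if (keep) {
      step_caches[[t]] <- out$caches
      dists[[t]] <- p
    }
    if (nxt == end_id) { truncated <- FALSE; break }
    cur <- nxt
  }
  n <- length(chosen)
  interior <- if (n && chosen[n] == end_id) chosen[-n] else chosen
  list(chosen_ids = chosen, interior_ids = interior,
       chosen_probs = probs, truncated = truncated,
       step_caches = step_caches, dists = dists,
       input_ids = c(start_id, if (n > 1L) chosen[1:(n - 1L)]))
}
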