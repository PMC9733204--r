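# Training machinery: analytic gradients for the full model, Adam, and the
# pretraining loop.

# ---- parameter trees -----------------------------------------------------

.gru_names <- c("Wr", "Ur", "br", "Wu", "Uu", "bu", "Wn", "Un", "bn")
.cell_names <- c("A", "D", "U", "R", "P")

.get_params <- function(model) {
  list(E = model$E,
       enc = lapply(model$enc, function(p) p[.cell_names]),
       W_mu = model$W_mu, b_mu = model$b_mu,
       W_lv = model$W_lv, b_lv = model$b_lv,
       dec = lapply(model$dec, function(p) p[.gru_names]),
       W_out = model$W_out, b_out = model$b_out)
}

.set_params <- function(model, values) {
  model$E <- values$E
  for (l in seq_along(model$enc)) model$enc[[l]][.cell_names] <- values$enc[[l]]
  model$W_mu <- values$W_mu; model$b_mu <- values$b_mu
  model$W_lv <- values$W_lv; model$b_lv <- values$b_lv
  for (l in seq_along(model$dec)) model$dec[[l]][.gru_names] <- values$dec[[l]]
  model$W_out <- values$W_out; model$b_out <- values$b_out
  model
}

.tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(.tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

.tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, .tree_scale, s = s))
  a * s
}

.zero_grads <- function(model) {
  list(E = model$E * 0,
       enc = lapply(model$enc, .zero_like_cell),
       W_mu = model$W_mu * 0, b_mu = model$b_mu * 0,
       W_lv = model$W_lv * 0, b_lv = model$b_lv * 0,
       dec = lapply(model$dec, .zero_like_gru),
       W_out = model$W_out * 0, b_out = model$b_out * 0)
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

# ---- decoder backward (shared by pretraining and RL) ---------------------

# inputs/targets are token-id vectors of equal length; weights is the
# per-step cross-entropy weight (1 for teacher forcing, the discounted
# reward for policy gradients); probs_list holds the emitted distributions
# and step_caches the per-layer GRU caches of each step.
.decoder_backward <- function(model, input_ids, targets, weights, probs_list,
                              step_caches) {
  L <- model$config$layers
  de <- model$config$embedding_dim
  dz <- model$config$latent_dim
  acc_dec <- lapply(model$dec, .zero_like_gru)
  gW_out <- model$W_out * 0
  gb_out <- model$b_out * 0
  gE <- model$E * 0
  gz <- numeric(dz)
  dh_carry <- replicate(L, numeric(model$config$hidden_size), simplify = FALSE)
  for (t in rev(seq_along(targets))) {
    if (weights[t] == 0 && all(vapply(dh_carry, function(v) all(v == 0), logical(1)))) next
    p <- probs_list[[t]]
    dlog <- weights[t] * p
    dlog[targets[t]] <- dlog[targets[t]] - weights[t]
    h_top <- step_caches[[t]][[L]]$h
    gW_out <- gW_out + outer(dlog, h_top)
    gb_out <- gb_out + dlog
    dh <- as.numeric(crossprod(model$W_out, dlog)) + dh_carry[[L]]
    for (l in L:1) {
      bb <- gru_backward(step_caches[[t]][[l]], dh, model$dec[[l]], acc_dec[[l]])
      acc_dec[[l]] <- bb$acc
      dh_carry[[l]] <- bb$dh_prev
      if (l > 1L) {
        dh <- bb$dx + dh_carry[[l - 1L]]
      } else {
        gE[, input_ids[t]] <- gE[, input_ids[t]] + bb$dx[seq_len(de)]
        gz <- gz + bb$dx[de + seq_len(dz)]
      }
    }
  }
  list(dec = acc_dec, W_out = gW_out, b_out = gb_out, E = gE, z = gz)
}

# ---- encoder backward ----------------------------------------------------

.encoder_backward <- function(model, ids, caches, dh_enc) {
  L <- model$config$layers
  de <- model$config$embedding_dim
  acc_enc <- lapply(model$enc, .zero_like_cell)
  gE <- model$E * 0
  dh_carry <- replicate(L, numeric(model$config$hidden_size), simplify = FALSE)
  dstack_carry <- replicate(L, NULL, simplify = FALSE)
  dh_carry[[L]] <- dh_enc
  for (t in rev(seq_along(ids))) {
    dh <- dh_carry[[L]]
    for (l in L:1) {
      bb <- .cell_backward(caches[[t]][[l]], dh, dstack_carry[[l]],
                           model$enc[[l]], acc_enc[[l]])
      acc_enc[[l]] <- bb$acc
      dh_carry[[l]] <- bb$dh_prev
      dstack_carry[[l]] <- bb$dstack_prev
      if (l > 1L) {
        dh <- bb$dx + dh_carry[[l - 1L]]
      } else {
        gE[, ids[t]] <- gE[, ids[t]] + bb$dx[seq_len(de)]
      }
    }
  }
  list(enc = acc_enc, E = gE)
}

# ---- one-sequence loss and gradients -------------------------------------

.train_step <- function(model, ids, cond3) {
  cfg <- model$config
  n <- length(ids)
  enc <- .encode_forward(model, ids, cond3, keep = TRUE)
  h_enc <- enc$h_final
  mu <- as.numeric(model$W_mu %*% h_enc + model$b_mu)
  lv <- as.numeric(model$W_lv %*% h_enc + model$b_lv)
  eps <- stats::rnorm(cfg$latent_dim)
  z <- mu + exp(lv / 2) * eps
  state <- .decoder_init(model)
  inputs <- ids[-n]
  targets <- ids[-1L]
  probs_list <- vector("list", length(targets))
  step_caches <- vector("list", length(targets))
  rec <- 0
  for (t in seq_along(inputs)) {
    out <- .decoder_step(model, inputs[t], z, cond3, state, keep = TRUE)
    state <- out$state
    probs_list[[t]] <- out$probs
    step_caches[[t]] <- out$caches
    rec <- rec - log(max(out$probs[targets[t]], 1e-12))
  }
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  klw <- cfg$kl_weight
  db <- .decoder_backward(model, inputs, targets,
                          rep(1, length(targets)), probs_list, step_caches)
  dmu <- klw * mu + db$z
  dlv <- klw * 0.5 * (exp(lv) - 1) + db$z * eps * 0.5 * exp(lv / 2)
  gW_mu <- outer(dmu, h_enc); gb_mu <- dmu
  gW_lv <- outer(dlv, h_enc); gb_lv <- dlv
  dh_enc <- as.numeric(crossprod(model$W_mu, dmu)) +
    as.numeric(crossprod(model$W_lv, dlv))
  eb <- .encoder_backward(model, ids, enc$caches, dh_enc)
  grads <- list(E = db$E + eb$E, enc = eb$enc,
                W_mu = gW_mu, b_mu = gb_mu, W_lv = gW_lv, b_lv = gb_lv,
                dec = db$dec, W_out = db$W_out, b_out = db$b_out)
  list(total = rec + klw * kl, reconstruction = rec, kl = kl, grads = grads)
}

#' Pretrain a stack-CVAE on a SMILES corpus
#'
#' Teacher-forced maximum-likelihood training of the conditional VAE: each
#' molecule is encoded with its own descriptor triple as the condition,
#' a latent code is drawn by reparameterized sampling, and the decoder is
#' trained to reconstruct the token sequence. The objective is summed token
#' cross entropy plus the closed-form Gaussian KL divergence, minimized with
#' Adam. Fully reproducible for a fixed seed.
#'
#' @param corpus Data.frame with columns `id`, `smiles` (ideally already
#'   passed through [filter_corpus()]).
#' @param config A `stack_cvae_config`.
#' @param epochs Number of passes over the corpus.
#' @param seed Integer seed controlling initialization, shuffling, and
#'   latent sampling.
#' @param verbose Print per-epoch loss.
#' @return List with `model` (the trained `stack_cvae`) and `curve`
#'   (data.frame `epoch`, `loss`, `reconstruction`, `kl`; per-sequence
#'   means).
#' @export
pretrain <- function(corpus, config, epochs = 10L, seed = 1L, verbose = FALSE) {
  if (is.null(corpus) || nrow(corpus) == 0L) stop("cannot pretrain on an empty corpus")
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  vocab <- build_vocabulary(corpus)
  conds <- compute_conditions_batch(corpus$smiles)
  ok <- stats::complete.cases(conds)
  if (!any(ok)) stop("no valid molecules in corpus")
  corpus <- corpus[ok, , drop = FALSE]
  conds <- conds[ok, , drop = FALSE]
  cstats <- condition_stats(conds)
  model <- build_model(vocab, config, cstats, seed = seed)
  ids_list <- lapply(corpus$smiles, function(s) .token_ids(tokenize(s, vocab), vocab))
  cond_list <- lapply(seq_len(nrow(conds)), function(i) {
    scale_conditions(stats::setNames(as.numeric(conds[i, ]),
                                     c("mol_weight", "logp", "tpsa")), cstats)
  })
  n <- length(ids_list)
  theta <- unlist(.get_params(model), use.names = FALSE)
  adam <- .adam_init(length(theta))
  skeleton <- .get_params(model)
  curve <- data.frame(epoch = integer(0), loss = numeric(0),
                      reconstruction = numeric(0), kl = numeric(0))
  if (epochs >= 1L) for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; tot_rec <- 0; tot_kl <- 0
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + config$batch_size - 1L, n)]
      grads <- NULL
      for (j in batch) {
        st <- .train_step(model, ids_list[[j]], cond_list[[j]])
        tot <- tot + st$total; tot_rec <- tot_rec + st$reconstruction
        tot_kl <- tot_kl + st$kl
        grads <- if (is.null(grads)) st$grads else .tree_add(grads, st$grads)
      }
      g <- unlist(grads, use.names = FALSE) / length(batch)
      upd <- .adam_step(theta, g, adam, config$learning_rate)
      theta <- upd$theta
      adam <- upd$state
      model <- .set_params(model, utils::relist(theta, skeleton))
      i <- i + config$batch_size
    }
    curve <- rbind(curve, data.frame(epoch = ep, loss = tot / n,
                                     reconstruction = tot_rec / n,
                                     kl = tot_kl / n))
    if (verbose) message(sprintf("epoch %d  loss %.4f (rec %.4f, kl %.4f)",
                                 ep, tot / n, tot_rec / n, tot_kl / n))
  }
  list(model = model, curve = curve)
}
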