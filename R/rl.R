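# Policy-gradient (REINFORCE) fine-tuning of the decoder.

#' Reinforcement-learning configuration
#'
#' @param gamma Discount rate in (0, 1]; default 0.1.
#' @param epochs Training epochs; default 500.
#' @param episodes_per_epoch Episodes sampled per gradient step; default 32.
#' @param learning_rate Adam learning rate for the decoder update.
#' @param max_len Maximum episode length in tokens (`NULL`: model default).
#' @param seed Integer seed.
#' @return List of class `rl_config`.
#' @export
rl_config <- function(gamma = 0.1, epochs = 500L, episodes_per_epoch = 32L,
                      learning_rate = 1e-3, max_len = NULL, seed = 1L) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  structure(list(gamma = gamma, epochs = as.integer(epochs),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 learning_rate = learning_rate,
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len),
                 seed = as.integer(seed)),
            class = "rl_config")
}

#' Per-step discounted rewards
#'
#' The terminal reward is attenuated geometrically toward the start of the
#' episode: step `t` (0-based) of an episode of length `T` receives
#' `total * gamma^(T - 1 - t)`, i.e. the full reward at the final step.
#'
#' @param total Terminal episode reward.
#' @param T Episode length (number of interior tokens); must be >= 1.
#' @param gamma Discount rate in (0, 1].
#' @return Numeric vector of length `T`.
#' @export
discount_rewards <- function(total, T, gamma) {
  if (T < 1L) stop("episode length must be at least 1")
  total * gamma^((T - 1):0)
}

#' Sample one policy episode
#'
#' Draws a fresh latent code from the standard-normal prior, generates a
#' SMILES autoregressively while recording the probability of each chosen
#' token, and computes the terminal reward for the finished molecule
#' (intermediate rewards are zero). The reward uses [total_reward()] over
#' the panel and oracles unless a custom `reward_fn(smiles)` is supplied.
#'
#' @param model A `stack_cvae` model.
#' @param cond Named condition vector (the reference drug's descriptors).
#' @param panel A `target_panel` (ignored when `reward_fn` is given).
#' @param oracles Oracle list from [make_mock_oracles()] / [get_oracles()].
#' @param gamma Discount rate for the per-step returns.
#' @param reward_fn Optional `function(smiles)` returning a numeric total
#'   reward or a `reward_components` list.
#' @param max_len Maximum episode length (`NULL`: model default).
#' @param seed Optional integer seed (scoped to this call).
#' @param keep Retain decoder caches for the gradient step (internal use).
#' @return List of class `episode_trace`: `tokens` (delimited character
#'   vector), `smiles`, `step_probs` (length `T`, interior tokens only),
#'   `discounted` (length `T`), `terminal_reward`, `truncated`.
#' @export
sample_episode <- function(model, cond, panel = NULL, oracles = NULL,
                           gamma = 0.1, reward_fn = NULL, max_len = NULL,
                           seed = NULL, keep = FALSE) {
  if (!is.null(seed)) {
    restore <- .Random.seed_guard(seed)
    on.exit(restore(), add = TRUE)
  }
  if (is.null(max_len)) max_len <- model$config$max_len
  z <- stats::rnorm(model$config$latent_dim)
  cond3 <- .scaled_cond(model, cond)
  ep <- .sample_tokens(model, z, cond3, max_len, keep = keep)
  smiles <- if (length(ep$interior_ids)) {
    paste(model$vocab$tokens[ep$interior_ids], collapse = "")
  } else ""
  rc <- if (!is.null(reward_fn)) {
    r <- reward_fn(smiles)
    if (is.numeric(r)) list(total = as.numeric(r)) else r
  } else {
    if (is.null(panel) || is.null(oracles))
      stop("either reward_fn or panel + oracles must be provided")
    total_reward(smiles, panel, oracles$affinity, oracles$synth)
  }
  T <- length(ep$interior_ids)
  disc <- if (T >= 1L) discount_rewards(rc$total, T, gamma) else numeric(0)
  toks <- c(START_TOKEN, model$vocab$tokens[ep$chosen_ids])
  if (ep$truncated) toks <- c(toks, END_TOKEN)  # close a truncated episode
  structure(list(tokens = toks, smiles = smiles,
                 step_probs = ep$chosen_probs[seq_len(T)],
                 discounted = disc, terminal_reward = rc,
                 truncated = ep$truncated, .raw = if (keep) ep else NULL,
                 .z = z, .cond3 = cond3),
            class = "episode_trace")
}

#' Policy-gradient loss of one episode
#'
#' `loss = -sum_t log(y_t) * discounted_t` over the interior tokens of the
#' episode, where `y_t` is the probability the policy assigned to the token
#' it actually emitted.
#'
#' @param trace An `episode_trace`.
#' @return The scalar loss.
#' @export
policy_gradient_loss <- function(trace) {
  y <- trace$step_probs
  if (length(y) == 0L) return(0)
  if (any(y <= 0)) stop("chosen-token probability of zero in episode trace")
  if (length(y) != length(trace$discounted))
    stop("step_probs and discounted returns differ in length")
  -sum(log(y) * trace$discounted)
}

#' Fine-tune the decoder with policy gradients
#'
#' REINFORCE over generated episodes: per epoch, `episodes_per_epoch`
#' molecules are sampled (fresh latent code from the prior each time,
#' condition vector fixed to the reference molecule), the discounted-return
#' weighted log-probability loss is accumulated, and an Adam step is taken
#' on the decoder parameters only (GRU layers and output head; encoder and
#' token embedding stay frozen). No variance-reduction baseline is used by
#' default.
#'
#' @param model A pretrained `stack_cvae`.
#' @param panel A `target_panel`.
#' @param oracles Oracle list (`affinity`, `synth`).
#' @param config An `rl_config`.
#' @param cond Named condition vector of the reference molecule.
#' @param reward_fn Optional custom `function(smiles)` reward (overrides
#'   panel/oracles).
#' @param baseline Subtract a running mean of episode rewards from the
#'   terminal reward before discounting (default `TRUE`). With strictly
#'   positive rewards and a heavily myopic discount, plain REINFORCE
#'   reinforces every sampled episode and measurably erodes the pretrained
#'   policy; the baseline restores a signed learning signal. Set `FALSE`
#'   for the unmodified estimator.
#' @param verbose Print per-epoch reward.
#' @return List with `model` (fine-tuned) and `curve` (data.frame `epoch`,
#'   `loss`, `mean_reward`, `mean_reward1/2/3`, `pct_valid`).
#' @export
finetune <- function(model, panel, oracles, config, cond, reward_fn = NULL,
                     baseline = TRUE, verbose = FALSE) {
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  sub_params <- function(mod) list(dec = lapply(mod$dec, function(p) p[.gru_names]),
                                   W_out = mod$W_out, b_out = mod$b_out)
  skeleton <- sub_params(model)
  theta <- unlist(skeleton, use.names = FALSE)
  curve <- data.frame()
  base_val <- 0
  n_seen <- 0
  if (config$epochs >= 1L) for (epch in seq_len(config$epochs)) {
    grads <- NULL
    losses <- numeric(config$episodes_per_epoch)
    rewards <- numeric(config$episodes_per_epoch)
    r123 <- matrix(NA_real_, config$episodes_per_epoch, 3L)
    valid <- logical(config$episodes_per_epoch)
    for (e in seq_len(config$episodes_per_epoch)) {
      tr <- sample_episode(model, cond, panel, oracles, gamma = config$gamma,
                           reward_fn = reward_fn, max_len = config$max_len,
                           keep = TRUE)
      rewards[e] <- tr$terminal_reward$total
      if (!is.null(tr$terminal_reward$reward1)) {
        r123[e, ] <- c(tr$terminal_reward$reward1, tr$terminal_reward$reward2,
                       tr$terminal_reward$reward3)
      }
      valid[e] <- isTRUE(tr$terminal_reward$valid) ||
        (is.null(tr$terminal_reward$valid) && nzchar(tr$smiles))
      losses[e] <- policy_gradient_loss(tr)
      ep <- tr$.raw
      R <- tr$terminal_reward$total
      adv <- if (baseline) R - base_val else R
      n_seen <- n_seen + 1
      base_val <- base_val + (R - base_val) / n_seen
      n_act <- length(ep$chosen_ids)
      if (n_act == 0L) next
      # the gradient step discounts over the full emitted action sequence,
      # end token included, so finishing an episode is itself reinforced
      w <- adv * config$gamma^((n_act - 1L):0L)
      g <- .decoder_backward(model, ep$input_ids, ep$chosen_ids, w,
                             ep$dists, ep$step_caches)
      g <- list(dec = g$dec, W_out = g$W_out, b_out = g$b_out)
      grads <- if (is.null(grads)) g else .tree_add(grads, g)
    }
    if (!is.null(grads)) {
      # plain SGD: with a stochastic REINFORCE gradient, adaptive
      # per-coordinate scaling mostly rescales sampling noise
      gv <- unlist(grads, use.names = FALSE) / config$episodes_per_epoch
      theta <- theta - config$learning_rate * gv
      vals <- utils::relist(theta, skeleton)
      for (l in seq_along(model$dec)) model$dec[[l]][.gru_names] <- vals$dec[[l]]
      model$W_out <- vals$W_out
      model$b_out <- vals$b_out
    }
    curve <- rbind(curve, data.frame(
      epoch = epch, loss = mean(losses), mean_reward = mean(rewards),
      mean_reward1 = mean(r123[, 1L], na.rm = TRUE),
      mean_reward2 = mean(r123[, 2L], na.rm = TRUE),
      mean_reward3 = mean(r123[, 3L], na.rm = TRUE),
      pct_valid = 100 * mean(valid)))
    if (verbose) message(sprintf("epoch %d  mean reward %.3f  loss %.3f",
                                 epch, mean(rewards), mean(losses)))
  }
  list(model = model, curve = curve)
}

#' Write an RL reward trace as CSV
#'
#' @param curve Curve data.frame from [finetune()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reward_trace <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
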