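test_that("encoding is deterministic with the right shape", {
  fit <- tiny_trained()
  model <- fit$model
  s <- generate_toy_corpus(1, seed = 11)$smiles[1]
  seq <- tokenize(s, model$vocab)
  cond <- compute_conditions(s)
  p1 <- encode(seq, cond, model)
  p2 <- encode(seq, cond, model)
  expect_identical(p1, p2)
  expect_length(p1$mean, model$config$latent_dim)
  expect_length(p1$log_variance, model$config$latent_dim)
})

test_that("a zero-weight model encodes everything to the prior", {
  v <- build_vocabulary(data.frame(smiles = "CCO"))
  model <- build_model(v, tiny_config(), NULL, zero_init = TRUE)
  p <- encode(tokenize("CCO", v), compute_conditions("CCO"), model)
  expect_identical(p$mean, rep(0, 4))
  expect_identical(p$log_variance, rep(0, 4))
})

test_that("latent sampling is reparameterized and seeded", {
  post <- list(mean = c(2, -1), log_variance = c(-30, -30))
  expect_equal(sample_latent(post, seed = 1), c(2, -1), tolerance = 1e-6)
  post2 <- list(mean = rep(0, 3), log_variance = rep(0, 3))
  expect_identical(sample_latent(post2, seed = 5), sample_latent(post2, seed = 5))
  # CLT bound on the sample mean of 10,000 standard-normal draws
  set.seed(3)
  draws <- replicate(10000, sample_latent(list(mean = 0, log_variance = 0)))
  expect_lt(abs(mean(draws)), 3 / sqrt(10000))
})

test_that("the CVAE objective decomposes into cross entropy plus Gaussian KL", {
  v <- build_vocabulary(data.frame(smiles = "CCO"))
  seq <- tokenize("CCO", v)
  targets <- seq$tokens[-1]
  onehot <- lapply(targets, function(tk) {
    p <- numeric(length(v$tokens)); p[v$index[[tk]]] <- 1; p
  })
  prior <- list(mean = 0, log_variance = 0)
  l <- cvae_loss(seq, prior, onehot, v)
  expect_identical(l$reconstruction, 0)
  expect_identical(l$kl, 0)
  expect_identical(l$total, 0)
  l2 <- cvae_loss(seq, list(mean = 1, log_variance = 0), onehot, v)
  expect_equal(l2$kl, 0.5)
  expect_error(cvae_loss(seq, prior, onehot[-1], v), "step distributions")
})

test_that("KL and reconstruction terms are always non-negative", {
  v <- build_vocabulary(data.frame(smiles = "CCO"))
  seq <- tokenize("CCO", v)
  set.seed(9)
  for (i in 1:25) {
    dists <- lapply(seq$tokens[-1], function(tk) {
      p <- runif(length(v$tokens)); p / sum(p)
    })
    post <- list(mean = rnorm(3), log_variance = rnorm(3))
    l <- cvae_loss(seq, post, dists, v)
    expect_gte(l$kl, 0)
    expect_gte(l$reconstruction, 0)
  }
})

test_that("zero pretraining epochs leave the model at initialization", {
  corp <- generate_toy_corpus(5, seed = 3)
  fit <- pretrain(corp, tiny_config(), epochs = 0, seed = 2)
  ref <- build_model(build_vocabulary(corp), tiny_config(),
                     condition_stats(compute_conditions_batch(corp$smiles)),
                     seed = 2)
  expect_identical(fit$model$E, ref$E)
  expect_identical(fit$model$W_out, ref$W_out)
  expect_identical(nrow(fit$curve), 0L)
})

test_that("pretraining is reproducible for a fixed seed", {
  corp <- generate_toy_corpus(8, seed = 3)
  f1 <- pretrain(corp, tiny_config(), epochs = 1, seed = 4)
  f2 <- pretrain(corp, tiny_config(), epochs = 1, seed = 4)
  expect_identical(f1$curve$loss, f2$curve$loss)
  expect_identical(f1$model$W_out, f2$model$W_out)
})

test_that("the model memorizes a single short molecule", {
  corp <- data.frame(id = "m1", smiles = "CCO", stringsAsFactors = FALSE)
  cfg <- tiny_config(learning_rate = 2e-2, batch_size = 1L)
  fit <- pretrain(corp, cfg, epochs = 200, seed = 1)
  expect_lt(tail(fit$curve$reconstruction, 1), 0.5)
  expect_lt(tail(fit$curve$loss, 1), head(fit$curve$loss, 1))
})

test_that("generation terminates, stays in-vocabulary, and is seeded", {
  fit <- tiny_trained()
  model <- fit$model
  cond <- ref_cond()
  s1 <- generate_smiles(model, cond, seed = 8)
  s2 <- generate_smiles(model, cond, seed = 8)
  expect_identical(as.character(s1), as.character(s2))
  for (seed in 1:10) {
    s <- generate_smiles(model, cond, max_len = 15, seed = seed)
    expect_lte(nchar(as.character(s)), 15 * max(nchar(model$vocab$tokens)))
    toks <- if (nzchar(s)) stackcvae:::.tokenize_chars(as.character(s)) else character(0)
    expect_true(all(toks %in% model$vocab$tokens))
  }
})

test_that("a decoder forced onto the end token emits the empty molecule", {
  v <- build_vocabulary(data.frame(smiles = "CCO"))
  model <- build_model(v, tiny_config(), NULL, zero_init = TRUE)
  model$b_out[v$index[[">"]]] <- 50
  s <- generate_smiles(model, c(mol_weight = 100, logp = 1, tpsa = 10), seed = 1)
  expect_identical(as.character(s), "")
  expect_false(attr(s, "truncated"))
})

test_that("the stack-less ablation runs the same pipeline end to end", {
  corp <- generate_toy_corpus(8, seed = 5)
  cfg <- tiny_config(use_stack = FALSE)
  fit <- pretrain(corp, cfg, epochs = 1, seed = 1)
  expect_equal(nrow(fit$curve), 1L)
  s <- generate_smiles(fit$model, ref_cond(), seed = 2)
  expect_true(is.character(as.character(s)))
})

test_that("checkpoints round-trip a model bit-for-bit", {
  fit <- tiny_trained()
  dir <- tempfile("ckpt")
  save_checkpoint(fit$model, dir)
  back <- load_checkpoint(dir)
  expect_identical(back$E, fit$model$E)
  expect_identical(back$vocab$tokens, fit$model$vocab$tokens)
  expect_identical(back$cond_stats$mean, fit$model$cond_stats$mean)
  s1 <- generate_smiles(fit$model, ref_cond(), seed = 42)
  s2 <- generate_smiles(back, ref_cond(), seed = 42)
  expect_identical(as.character(s1), as.character(s2))
})
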