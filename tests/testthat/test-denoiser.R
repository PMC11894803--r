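test_that("configuration constraints are enforced", {
  expect_error(denoiser_config(embed_dim = 30L, n_heads = 4L), "divisible")
  expect_error(denoiser_config(embed_dim = 33L, n_heads = 1L), "even")
  expect_error(denoiser_config(dropout = 0.1), "dropout")
  cfg <- denoiser_config(embed_dim = 32L)
  expect_equal(cfg$feedforward_dim, 128L)
})

test_that("forward output shape equals input shape across gene counts", {
  cfg <- denoiser_config(embed_dim = 16L, n_blocks = 1L, n_heads = 2L,
                         feedforward_dim = 32L)
  for (G in c(8L, 33L, 256L)) {
    model <- init_denoiser(cfg, G, seed = 1)
    dn <- denoiser_fun(model)
    out <- dn(matrix(0.1, 5, G), rep(3L, 5), rep(1L, 5))
    expect_identical(dim(out), c(5L, G))
  }
  model <- init_denoiser(cfg, 16L, seed = 1)
  expect_error(denoiser_fun(model)(matrix(0, 2, 8), c(1L, 1L), c(1L, 1L)),
               "expects 16")
})

test_that("initialization is seed-deterministic", {
  cfg <- denoiser_config(embed_dim = 16L, n_blocks = 1L, n_heads = 2L)
  m1 <- init_denoiser(cfg, 10L, seed = 7)
  m2 <- init_denoiser(cfg, 10L, seed = 7)
  x <- matrix(runif(30, -1, 1), 3, 10)
  expect_identical(denoiser_fun(m1, "raw")(x, rep(2L, 3), rep(1L, 3)),
                   denoiser_fun(m2, "raw")(x, rep(2L, 3), rep(1L, 3)))
  m3 <- init_denoiser(cfg, 10L, seed = 8)
  expect_false(identical(m1$params$in_w, m3$params$in_w))
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("phenobridge")
  cfg <- denoiser_config(embed_dim = 8L, n_blocks = 1L, n_heads = 2L,
                         feedforward_dim = 16L)
  set.seed(42)
  model <- init_denoiser(cfg, 4L, seed = 9)
  p <- model$params
  p$out_w <- rnorm(length(p$out_w), sd = 0.5)  # non-zero head: gradients flow
  x <- matrix(runif(12, -1, 1), 3, 4)
  t <- c(3L, 7L, 1L); cond <- c(1L, 2L, 1L)
  target <- matrix(rnorm(12), 3, 4)
  loss_of <- function(pp)
    mean((ns$.dn_forward(pp, cfg, x, t, cond) - target)^2)
  fw <- ns$.dn_forward(p, cfg, x, t, cond, keep_cache = TRUE)
  gr <- ns$.dn_backward(p, cfg, fw$cache, cond,
                        2 * (fw$eps_hat - target) / length(target))
  h <- 1e-6
  for (k in c("in_w", "pos", "cond", "t_w1", "out_w",
              "blk1_wq", "blk1_wv", "blk1_w1", "blk1_ln1_g")) {
    for (i in seq_len(min(length(p[[k]]), 6))) {
      pp <- p; pp[[k]][i] <- p[[k]][i] + h; up <- loss_of(pp)
      pp[[k]][i] <- p[[k]][i] - h; dn <- loss_of(pp)
      num <- (up - dn) / (2 * h)
      expect_equal(gr[[k]][i], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("training reduces the loss, records a trace, and is seeded", {
  tt <- tiny_trained()
  tr <- tt$model$loss_trace
  expect_length(tr, 300)
  expect_true(all(tr >= 0))
  expect_lt(mean(tail(tr, 50)), tr[1])
  # conditioning became informative: outputs differ across condition index
  dn <- denoiser_fun(tt$model)
  x <- tt$pp$train$values[1:4, ]
  out1 <- dn(x, rep(10L, 4), rep(1L, 4))
  out2 <- dn(x, rep(10L, 4), rep(2L, 4))
  expect_gt(max(abs(out1 - out2)), 0)
  # identical seed reruns give identical traces
  model2 <- init_denoiser(tt$model$config, 8L, seed = 3L)
  model2 <- train_denoiser(model2, tt$pp$train, tt$schedule,
                           train_options(16L, 1e-3, 25L, ema_decay = 0.99,
                                         seed = 3L))
  model3 <- init_denoiser(tt$model$config, 8L, seed = 3L)
  model3 <- train_denoiser(model3, tt$pp$train, tt$schedule,
                           train_options(16L, 1e-3, 25L, ema_decay = 0.99,
                                         seed = 3L))
  expect_identical(model2$loss_trace, model3$loss_trace)
  expect_identical(model2$params, model3$params)
})

test_that("training rejects unlabeled or unnormalized data", {
  tt <- tiny_trained()
  bad <- gem(tt$pp$train$values * 5, labels = tt$pp$train$labels)
  expect_error(train_denoiser(init_denoiser(tt$model$config, 8L, 1L),
                              bad, tt$schedule,
                              train_options(8L, 1e-3, 5L)),
               "normalized")
  unlab <- gem(tt$pp$train$values)
  expect_error(train_denoiser(init_denoiser(tt$model$config, 8L, 1L),
                              unlab, tt$schedule,
                              train_options(8L, 1e-3, 5L)),
               "label")
})

test_that("checkpoints restore bit-identical sampling", {
  tt <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tt$model, tt$schedule, tt$pp$scaler,
                  colnames(tt$pp$train$values), path)
  ck <- load_checkpoint(path)
  expect_identical(ck$gene_ids, colnames(tt$pp$train$values))
  expect_identical(ck$label_levels, tt$model$label_levels)
  before <- ancestral_sample(denoiser_fun(tt$model), 4, 8, 1L, tt$schedule,
                             seed = 13)
  after <- ancestral_sample(denoiser_fun(ck$model), 4, 8, 1L, ck$schedule,
                            seed = 13)
  expect_identical(before, after)
  # corrupted file fails loudly
  writeLines("not a checkpoint", path)
  expect_error(load_checkpoint(path), "checkpoint")
})
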