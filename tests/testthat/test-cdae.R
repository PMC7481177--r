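# Small, fast training runs; the full desk-scale denoising experiment lives
# in the acceptance suite.

small_pairs <- function(n_records = 56, seed = 17) {
  with_cache(paste0("cdae_pairs_", n_records, "_", seed), {
    recs <- simulate_ppg_dataset(n_records, noise_factors = 0.001, seed = seed)
    cdae_pairs(preprocess_records(recs), seed = seed)
  })
}

test_that("the configuration encodes the compression contract", {
  cfg <- cdae_config()
  expect_equal(cfg$latent_length, 100L)
  expect_lt(cfg$latent_length, cfg$input_length)
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$lr_patience, 25L)
  expect_equal(cfg$lr_decrement, 0.001)
  expect_error(cdae_config(input_length = 801), "divisible")
})

test_that("two builds from the same seed are identical", {
  a <- build_cdae(cdae_config(seed = 4))
  b <- build_cdae(cdae_config(seed = 4))
  expect_identical(a$layers, b$layers)
  # ReLU activations in all hidden layers, linear reconstruction output
  acts <- vapply(a$layers, function(l)
    if (is.null(l$activation)) "" else l$activation, "")
  convs <- acts[acts != ""]
  expect_true(all(convs[-length(convs)] == "relu"))
  expect_equal(convs[length(convs)], "linear")
})

test_that("batch corruption pairs each window with a scaled noise factor", {
  X <- matrix(rnorm(6 * 800, 10, 2), 6, 800)
  set.seed(5)
  cb0 <- corrupt_batch(X, factors = 0)
  expect_equal(cb0$corrupted, X)
  expect_error(corrupt_batch(X, factors = numeric(0)), "factors")
  set.seed(5)
  cb <- corrupt_batch(X, factors = noise_factors())
  expect_equal(sort(unique(cb$noise_factor)), sort(noise_factors()[1:6]))
  for (i in seq_len(6)) {
    ratio <- sd(cb$corrupted[i, ] - X[i, ]) /
      (cb$noise_factor[i] * sd(X[i, ]))
    expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  }
})

mse_ref <- function(a, b) mean((a - b)^2)

test_that("training reduces validation error and logs a full history", {
  m <- build_cdae(cdae_config(epochs = 4, seed = 9))
  fit <- train_cdae(m, small_pairs())
  h <- tidy(fit)
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$train_mse)), all(is.finite(h$val_mse)))
  expect_lt(h$val_mse[4], h$val_mse[1])
  expect_identical(mse_ref(matrix(1:4, 2), matrix(1:4, 2)), 0)
})

test_that("the plateau schedule decrements the learning rate additively", {
  cfg <- cdae_config(epochs = 4, lr_patience = 1, lr_decrement = 4e-4,
                     lr_floor = 1e-4, seed = 13)
  # constant targets make improvement stall quickly at tiny scale
  m <- build_cdae(cfg)
  p <- small_pairs()[1:40, ]
  fit <- train_cdae(m, p)
  lrs <- tidy(fit)$lr
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= cfg$lr_floor))
  drops <- unique(round(diff(unique(lrs)), 10))
  if (length(drops)) expect_true(all(drops == -cfg$lr_decrement))
})

test_that("reconstruction preserves shape and batch composition", {
  m <- build_cdae(cdae_config(seed = 2))
  p <- small_pairs()
  X <- do.call(rbind, p$samples[1:5])
  Z <- reconstruct(m, X)
  expect_equal(dim(Z), dim(X))
  expect_true(all(is.finite(Z)))
  z1 <- reconstruct(m, X[3, ])
  expect_equal(as.numeric(Z[3, ]), as.numeric(z1), tolerance = 1e-6)
  expect_error(reconstruct(m, X[, 1:700]), "length")
})

test_that("the extracted encoder reproduces the autoencoder's latent map", {
  m <- build_cdae(cdae_config(seed = 8))
  enc <- extract_encoder(m)
  expect_length(enc$weights, 3)
  expect_true(all(vapply(enc$weights, function(w)
    is.matrix(w$W) && is.numeric(w$b), TRUE)))
  f <- tempfile(fileext = ".rds")
  saveRDS(enc, f)
  expect_identical(readRDS(f), enc)
  # re-applying the weights to a fresh autoencoder gives identical encodings
  m2 <- build_cdae(cdae_config(seed = 999))
  for (j in 1:3) {
    m2$layers[[m2$encoder_idx[j]]]$W <- enc$weights[[j]]$W
    m2$layers[[m2$encoder_idx[j]]]$b <- enc$weights[[j]]$b
  }
  X <- do.call(rbind, small_pairs()$samples[1:4])
  expect_equal(encode(m, X), encode(m2, X), tolerance = 1e-7)
})
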