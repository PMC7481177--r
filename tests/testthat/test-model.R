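trained_encoder <- function() {
  with_cache("enc_small", {
    m <- build_cdae(cdae_config(epochs = 2, seed = 41))
    recs <- simulate_ppg_dataset(42, noise_factors = 0.001, seed = 41)
    fit <- train_cdae(m, cdae_pairs(preprocess_records(recs), seed = 41))
    extract_encoder(fit)
  })
}

test_that("variants expose the advertised heads and a six-layer trunk", {
  mt <- build_afnet("MT_RANDOM", seed = 1)
  st <- build_afnet("ST_RANDOM", seed = 1)
  expect_false(is.null(mt$qa_arm))
  expect_false(is.null(mt$event_arm))
  expect_true(is.null(st$qa_arm))
  expect_false(is.null(st$event_arm))
  n_conv <- sum(vapply(mt$trunk, function(l) l$kind == "conv", TRUE))
  expect_equal(n_conv, 6L)
  n_par <- get("n_params", envir = getNamespace("ppgnet"))
  expect_gt(n_par(mt), n_par(st))
  expect_identical(build_afnet("MT_RANDOM", seed = 1)$trunk, mt$trunk)
  expect_error(build_afnet("BOGUS"), "variant")
})

test_that("encoder transfer is exact, idempotent and guarded by variant", {
  enc <- trained_encoder()
  m <- build_afnet("MT_PRETRAINED", seed = 3)
  m <- transfer_encoder_weights(m, enc)
  expect_true(m$transferred)
  for (j in 1:3) {
    expect_identical(m$trunk[[m$encoder_pos[j]]]$W, enc$weights[[j]]$W)
    expect_identical(m$trunk[[m$encoder_pos[j]]]$b, enc$weights[[j]]$b)
  }
  expect_identical(transfer_encoder_weights(m, enc)$trunk, m$trunk)
  expect_error(transfer_encoder_weights(build_afnet("MT_RANDOM", seed = 3), enc),
               "random")
  bad <- enc
  bad$weights[[1]]$W <- bad$weights[[1]]$W[, 1:8]
  expect_error(transfer_encoder_weights(build_afnet("MT_PRETRAINED", seed = 3),
                                        bad), "mismatch")
})

test_that("after transfer the trunk reproduces the encoder's activations", {
  enc <- trained_encoder()
  m <- build_afnet("MT_PRETRAINED", seed = 6, encoder = enc)
  w <- fixture_windows()
  X <- do.call(rbind, w$samples[1:20])
  # trunk layers 1-6 are exactly the conv+pool encoder stages
  pn <- getNamespace("ppgnet")
  tr_act <- pn$nn_forward(m$trunk[1:6], pn$as_engine_batch(X), nrow(X),
                          ncol(X), FALSE)$out
  cd <- build_cdae(cdae_config(seed = 123))
  for (j in 1:3) {
    cd$layers[[cd$encoder_idx[j]]]$W <- enc$weights[[j]]$W
    cd$layers[[cd$encoder_idx[j]]]$b <- enc$weights[[j]]$b
  }
  enc_act <- encode(cd, X)
  expect_lt(max(abs(matrix(tr_act, nrow(X)) - enc_act)), 1e-6)
})

test_that("training validates labels and task weights", {
  w <- fixture_windows()[1:60, ]
  m <- build_afnet("ST_RANDOM", seed = 2)
  one_class <- w
  one_class$rhythm <- factor("AF", levels = c("SINUS", "AF"))
  expect_error(train_afnet(m, one_class, epochs = 1), "single rhythm class")
  no_labels <- w
  no_labels$rhythm <- NULL
  expect_error(train_afnet(m, no_labels, epochs = 1), "rhythm")
  expect_error(train_afnet(m, w, epochs = 1, w_af = -1), "w_qa/w_af")
  mq <- build_afnet("MT_RANDOM", seed = 2)
  expect_error(suppressWarnings(train_afnet(mq, w, epochs = 1, w_qa = 0,
                                            w_af = 0)),
               "at least one")
})

test_that("a multitask graph with zero quality weight follows the single-task trajectory", {
  set.seed(44)
  w <- fixture_windows()[sample(420, 120), ]
  st <- train_afnet(build_afnet("ST_RANDOM", seed = 7), w, epochs = 1,
                    seed = 7)
  mt <- suppressWarnings(
    train_afnet(build_afnet("MT_RANDOM", seed = 7), w, epochs = 1,
                w_qa = 0, seed = 7))
  expect_equal(tidy(mt)$train_loss_af[1], tidy(st)$train_loss_af[1],
               tolerance = 1e-10)
})

test_that("quality-only gradients leave the event arm untouched", {
  set.seed(45)
  w <- fixture_windows()[sample(420, 120), ]
  m <- build_afnet("MT_RANDOM", seed = 8)
  before <- m$event_arm
  fit <- suppressWarnings(train_afnet(m, w, epochs = 1, w_af = 0, seed = 8))
  # trainable parameters untouched (running batch-norm statistics are
  # recalibrated for every arm after training, so compare weights only)
  trainable <- function(lys) lapply(lys, function(ly) ly[intersect(
    c("W", "b", "gamma", "beta"), names(ly))])
  expect_identical(trainable(fit$event_arm), trainable(before))
  expect_false(identical(trainable(fit$qa_arm), trainable(m$qa_arm)))
})

test_that("prediction is a deterministic simplex, invariant to batching", {
  ff <- fixture_fit()
  p <- predict(ff$fit, ff$windows[1:40, ])
  expect_true(all(abs(p$af_prob_SINUS + p$af_prob_AF - 1) < 1e-6))
  expect_true(all(abs(p$qa_prob_EXCELLENT + p$qa_prob_ACCEPTABLE +
                        p$qa_prob_POOR - 1) < 1e-6))
  expect_identical(p$af_pred,
                   factor(c("SINUS", "AF")[1 + (p$af_prob_AF > p$af_prob_SINUS)],
                          levels = c("SINUS", "AF")))
  p2 <- predict(ff$fit, ff$windows[1:40, ])
  expect_identical(p, p2)
  X <- do.call(rbind, ff$windows$samples[1:40])
  one_by_one <- do.call(rbind, lapply(1:5, function(i)
    as.matrix(predict(ff$fit, X[i, , drop = FALSE])[, 1:2])))
  expect_lt(max(abs(one_by_one -
                      as.matrix(predict(ff$fit, X[1:5, , drop = FALSE])[, 1:2]))),
            1e-5)
})

test_that("embeddings come from the last dense layer before prediction", {
  ff <- fixture_fit()
  E <- embed_windows(ff$fit, ff$windows[1:12, ])
  expect_equal(dim(E), c(12L, 64L))
  expect_true(all(is.finite(E)))
  X <- do.call(rbind, ff$windows$samples[c(3, 3)])
  E2 <- embed_windows(ff$fit, X)
  expect_equal(E2[1, ], E2[2, ])
  expect_error(embed_windows(build_afnet("ST_QA", seed = 1), X), "event arm")
})

test_that("model selection tracks the best validation F1", {
  ff <- fixture_fit()
  h <- tidy(ff$fit)
  expect_equal(glance(ff$fit)$best_val_f1, max(h$val_f1))
  expect_true(ff$fit$trained)
})
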