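# The network engine is validated against numerical differentiation: if any
# layer's backward pass were wrong, these checks would fail by orders of
# magnitude (the kernels run in single precision, hence the tolerances).

engine <- function(name) get(name, envir = getNamespace("ppgnet"))

build_test_stack <- function() {
  nn_init <- engine("nn_init")
  nn_init(list(
    engine("nn_conv")(1L, 4L, 5L, "relu"), engine("nn_pool")(),
    engine("nn_conv")(4L, 3L, 3L, "leaky"), engine("nn_bn")(3L),
    engine("nn_pool")(),
    engine("nn_upsample")(), engine("nn_conv")(3L, 2L, 3L, "linear"),
    engine("nn_flatten")(), engine("nn_dense")(16L, 5L, "relu"),
    engine("nn_dense")(5L, 2L, "linear")
  ))
}

test_that("backpropagated gradients match numerical differentiation", {
  nn_forward <- engine("nn_forward")
  nn_backward <- engine("nn_backward")
  ce <- engine("ce_loss_grad")
  set.seed(42)
  n <- 3L; L <- 16L
  layers <- build_test_stack()
  x <- matrix(rnorm(n * L), n * L, 1)
  y <- sample(1:2, n, TRUE)
  sw <- runif(n, 0.5, 1.5); sw <- sw / mean(sw)
  loss_of <- function(lys) ce(nn_forward(lys, x, n, L, TRUE)$out, y, sw)$loss
  fw <- nn_forward(layers, x, n, L, TRUE)
  lo <- ce(fw$out, y, sw)
  bw <- nn_backward(fw$layers, fw$caches, lo$dlogits, n)
  eps <- 1e-3
  for (i in seq_along(layers)) {
    g <- bw$grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- layers[[i]][[nm]]
      for (j in sample(seq_along(p), min(6, length(p)))) {
        l2 <- layers
        l2[[i]][[nm]][j] <- p[j] + eps
        f1 <- loss_of(l2)
        l2[[i]][[nm]][j] <- p[j] - eps
        f0 <- loss_of(l2)
        num <- (f1 - f0) / (2 * eps)
        # relative error with an absolute floor (single-precision conv path)
        err <- abs(num - g[[nm]][j]) / max(0.05, abs(num) + abs(g[[nm]][j]))
        expect_lt(err, 0.02)
      }
    }
  }
})

test_that("input gradients and the MSE path are correct", {
  nn_forward <- engine("nn_forward")
  nn_backward <- engine("nn_backward")
  mse <- engine("mse_loss_grad")
  nn_init <- engine("nn_init")
  set.seed(7)
  n <- 3L; L <- 16L
  layers <- nn_init(list(
    engine("nn_conv")(1L, 3L, 5L, "relu"), engine("nn_pool")(),
    engine("nn_upsample")(), engine("nn_conv")(3L, 1L, 5L, "linear")
  ))
  x <- matrix(rnorm(n * L), n * L, 1)
  tgt <- matrix(rnorm(n * L), n * L, 1)
  fw <- nn_forward(layers, x, n, L, TRUE)
  lo <- mse(fw$out, tgt)
  bw <- nn_backward(layers, fw$caches, lo$dz, n)
  eps <- 1e-3
  for (j in sample(seq_along(x), 10)) {
    x2 <- x
    x2[j] <- x[j] + eps
    f1 <- mse(nn_forward(layers, x2, n, L, TRUE)$out, tgt)$loss
    x2[j] <- x[j] - eps
    f0 <- mse(nn_forward(layers, x2, n, L, TRUE)$out, tgt)$loss
    num <- (f1 - f0) / (2 * eps)
    err <- abs(num - bw$dx[j]) / max(0.05, abs(num) + abs(bw$dx[j]))
    expect_lt(err, 0.02)
  }
  for (i in seq_along(layers)) {
    g <- bw$grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- layers[[i]][[nm]]
      for (j in sample(seq_along(p), min(6, length(p)))) {
        l2 <- layers
        l2[[i]][[nm]][j] <- p[j] + eps
        f1 <- mse(nn_forward(l2, x, n, L, TRUE)$out, tgt)$loss
        l2[[i]][[nm]][j] <- p[j] - eps
        f0 <- mse(nn_forward(l2, x, n, L, TRUE)$out, tgt)$loss
        num <- (f1 - f0) / (2 * eps)
        err <- abs(num - g[[nm]][j]) / max(0.05, abs(num) + abs(g[[nm]][j]))
        expect_lt(err, 0.02)
      }
    }
  }
})

test_that("layer shape contracts hold through a forward pass", {
  nn_forward <- engine("nn_forward")
  nn_init <- engine("nn_init")
  set.seed(1)
  n <- 2L; L <- 32L
  layers <- nn_init(list(engine("nn_conv")(1L, 4L, 5L, "relu"),
                         engine("nn_pool")(), engine("nn_upsample")()))
  fw <- nn_forward(layers, matrix(rnorm(n * L), n * L, 1), n, L, FALSE)
  expect_equal(fw$L, L)            # pool halves, upsample restores
  expect_equal(dim(fw$out), c(n * L, 4L))
  expect_true(all(is.finite(fw$out)))
})

test_that("initialisation is a pure function of the RNG seed", {
  nn_init <- engine("nn_init")
  spec <- list(engine("nn_conv")(1L, 4L, 5L, "relu"),
               engine("nn_dense")(8L, 2L, "linear"))
  set.seed(99); a <- nn_init(spec)
  set.seed(99); b <- nn_init(spec)
  expect_identical(a, b)
})
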