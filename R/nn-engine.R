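# Internal 1-D CNN engine.
#
# A batch of n windows of length L with C channels lives in an (n*L) x C
# matrix, row r = i + n*(l-1); this is the column-major flattening of an
# (n, L, C) array, so reshapes to/from the flat dense view are free.
# Heavy kernels (convolution, pooling, upsampling) are compiled (src/).
# All randomness (init, shuffling, dropout) draws from R's global RNG so a
# single set.seed() makes training bit-reproducible on a fixed thread count.

nn_conv <- function(in_ch, out_ch, kernel, activation = "relu") {
  stopifnot(kernel %% 2 == 1, in_ch >= 1, out_ch >= 1)
  structure(list(kind = "conv", in_ch = in_ch, out_ch = out_ch,
                 kernel = kernel, activation = activation,
                 W = NULL, b = NULL), class = "nn_layer")
}

nn_pool <- function(factor = 2L) {
  stopifnot(factor == 2L)
  structure(list(kind = "pool", factor = 2L), class = "nn_layer")
}

nn_upsample <- function(factor = 2L) {
  stopifnot(factor == 2L)
  structure(list(kind = "upsample", factor = 2L), class = "nn_layer")
}

nn_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  structure(list(kind = "bn", ch = ch, momentum = momentum, eps = eps,
                 gamma = rep(1, ch), beta = rep(0, ch),
                 run_mean = rep(0, ch), run_var = rep(1, ch)),
            class = "nn_layer")
}

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  structure(list(kind = "dropout", rate = rate), class = "nn_layer")
}

nn_flatten <- function() structure(list(kind = "flatten"), class = "nn_layer")

nn_dense <- function(in_dim, out_dim, activation = "relu") {
  structure(list(kind = "dense", in_dim = in_dim, out_dim = out_dim,
                 activation = activation, W = NULL, b = NULL),
            class = "nn_layer")
}

# He-normal initialisation of every parameterised layer, from the global RNG.
nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- ly$kernel * ly$in_ch
      ly$W <- matrix(stats::rnorm(fan_in * ly$out_ch, 0, sqrt(2 / fan_in)),
                     fan_in, ly$out_ch)
      ly$b <- rep(0, ly$out_ch)
    } else if (ly$kind == "dense") {
      ly$W <- matrix(stats::rnorm(ly$in_dim * ly$out_dim, 0,
                                  sqrt(2 / ly$in_dim)),
                     ly$in_dim, ly$out_dim)
      ly$b <- rep(0, ly$out_dim)
    }
    layers[[i]] <- ly
  }
  layers
}

act_code <- function(activation) {
  switch(activation, linear = 0L, relu = 1L, leaky = 2L,
         stop("unknown activation: ", activation))
}

nn_act <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         leaky = ifelse(x > 0, x, 0.3 * x),
         linear = x,
         stop("unknown activation: ", activation))
}

nn_act_grad <- function(out, dout, activation) {
  switch(activation,
         relu = dout * (out > 0),
         leaky = dout * ifelse(out > 0, 1, 0.3),
         linear = dout,
         stop("unknown activation: ", activation))
}

# Forward pass through a layer sequence.  `x` is (n*L) x C (or n x D once
# flattened).  Returns output, per-layer caches for backprop, and the layer
# list itself (batch-norm statistics are updated in some modes).
#
# Modes: "train" (batch-norm batch statistics, dropout active),
# "calibrate" (batch statistics accumulated into the running estimates,
# dropout off — used to re-estimate inference statistics after training,
# since statistics collected under dropout noise do not match the
# dropout-free inference activations), "batch_eval" (batch statistics,
# nothing updated, dropout off — stable mid-training validation) and
# "infer" (running statistics, dropout off).  TRUE/FALSE are accepted as
# aliases for "train"/"infer".
nn_forward <- function(layers, x, n, L, mode = "infer") {
  if (isTRUE(mode)) mode <- "train"
  if (isFALSE(mode)) mode <- "infer"
  caches <- vector("list", length(layers))
  flat <- FALSE
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      cf <- conv1d_fwd(x, ly$W, ly$b, n, L, ly$kernel, act_code(ly$activation))
      caches[[i]] <- list(xc = cf$xc, out = cf$Y, L = L)
      x <- cf$Y
    } else if (ly$kind == "pool") {
      mp <- maxpool2_fwd(x, n, L)
      caches[[i]] <- list(mask = mp$mask, Lo = L / 2)
      x <- mp$Y
      L <- L / 2
    } else if (ly$kind == "upsample") {
      caches[[i]] <- list(L = L)
      x <- upsample2_fwd(x, n, L)
      L <- 2 * L
    } else if (ly$kind == "bn") {
      if (mode != "infer") {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc * xc)
        inv_std <- 1 / sqrt(v + ly$eps)
        xhat <- sweep(xc, 2, inv_std, `*`)
        if (mode == "train") {
          ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
          ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
          layers[[i]] <- ly
        } else if (mode == "calibrate") {
          ly$acc_mean <- (ly$acc_mean %||% 0) + mu
          ly$acc_var <- (ly$acc_var %||% 0) + v
          ly$acc_n <- (ly$acc_n %||% 0L) + 1L
          layers[[i]] <- ly
        }
      } else {
        inv_std <- 1 / sqrt(ly$run_var + ly$eps)
        xhat <- sweep(sweep(x, 2, ly$run_mean), 2, inv_std, `*`)
      }
      out <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
      caches[[i]] <- list(xhat = xhat, inv_std = inv_std,
                          training = mode != "infer")
      x <- out
    } else if (ly$kind == "dropout") {
      if (mode == "train" && ly$rate > 0) {
        mask <- (stats::runif(length(x)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(x)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$kind == "flatten") {
      caches[[i]] <- list(n = n, L = L, C = ncol(x))
      dim(x) <- c(n, L * ncol(x))
      flat <- TRUE
    } else if (ly$kind == "dense") {
      pre <- x %*% ly$W
      pre <- sweep(pre, 2, ly$b, `+`)
      out <- nn_act(pre, ly$activation)
      caches[[i]] <- list(x = x, out = out)
      x <- out
    }
  }
  list(out = x, caches = caches, layers = layers, n = n, L = L, flat = flat)
}

# Backward pass.  Returns the gradient w.r.t. the sequence input and a list
# of per-layer parameter gradients (NULL for parameter-free layers).  With
# `need_input_grad = FALSE` the gradient below the first layer is skipped
# (the first layer of a network has nothing underneath).
nn_backward <- function(layers, caches, dout, n, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$kind == "conv") {
      bw <- conv1d_bwd(cc$xc, ly$W, dout, cc$out, n, cc$L, ly$kernel,
                       act_code(ly$activation),
                       i > 1L || need_input_grad)
      grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
      dout <- bw$dX
    } else if (ly$kind == "pool") {
      dout <- maxpool2_bwd(dout, cc$mask, n, cc$Lo)
    } else if (ly$kind == "upsample") {
      dout <- upsample2_bwd(dout, n, 2 * cc$L)
    } else if (ly$kind == "bn") {
      dgamma <- colSums(dout * cc$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, ly$gamma, `*`)
      if (cc$training) {
        # batch statistics participate in the forward pass
        m <- nrow(dout)
        dx <- sweep(dxhat -
                      matrix(colMeans(dxhat), m, ncol(dout), byrow = TRUE) -
                      cc$xhat * matrix(colMeans(dxhat * cc$xhat), m,
                                       ncol(dout), byrow = TRUE),
                    2, cc$inv_std, `*`)
      } else {
        # inference mode is a fixed per-channel affine map
        dx <- sweep(dxhat, 2, cc$inv_std, `*`)
      }
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dout <- dx
    } else if (ly$kind == "dropout") {
      if (!is.null(cc$mask)) dout <- dout * cc$mask
    } else if (ly$kind == "flatten") {
      dim(dout) <- c(cc$n * cc$L, cc$C)
    } else if (ly$kind == "dense") {
      dpre <- nn_act_grad(cc$out, dout, ly$activation)
      grads[[i]] <- list(W = crossprod(cc$x, dpre), b = colSums(dpre))
      dout <- tcrossprod(dpre, ly$W)
    }
  }
  list(dx = dout, grads = grads)
}

# Fold accumulated calibration statistics into the running estimates.
nn_bn_finalize <- function(layers) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "bn" && !is.null(ly$acc_n) && ly$acc_n > 0) {
      ly$run_mean <- ly$acc_mean / ly$acc_n
      ly$run_var <- ly$acc_var / ly$acc_n
      ly$acc_mean <- ly$acc_var <- ly$acc_n <- NULL
      layers[[i]] <- ly
    }
  }
  layers
}

nn_param_names <- function(ly) {
  switch(ly$kind, conv = , dense = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

# Flat snapshot of all parameters (including batch-norm running stats) for
# checkpointing; nn_set_params restores them.
nn_get_params <- function(layers) {
  lapply(layers, function(ly) {
    nm <- nn_param_names(ly)
    if (ly$kind == "bn") nm <- c(nm, "run_mean", "run_var")
    if (!length(nm)) return(NULL)
    ly[nm]
  })
}

nn_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(params[[i]])) {
      for (nm in names(params[[i]])) layers[[i]][[nm]] <- params[[i]][[nm]]
    }
  }
  layers
}

# Adam state and update, applied layer-wise over a list of gradient lists.
adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nm <- nn_param_names(ly)
    if (!length(nm)) return(NULL)
    st <- lapply(ly[nm], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      layers[[i]][[nm]] <- layers[[i]][[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Softmax cross-entropy with optional per-sample weights (mean-one scaled).
softmax_probs <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

ce_loss_grad <- function(logits, y, sample_w = NULL, loss_w = 1) {
  n <- nrow(logits)
  if (is.null(sample_w)) sample_w <- rep(1, n)
  p <- softmax_probs(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -sum(sample_w * log(pmax(p[idx], 1e-12))) / n
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  dlog <- dlog * (sample_w / n) * loss_w
  list(loss = loss * loss_w, dlogits = dlog, probs = p)
}

mse_loss_grad <- function(z, x, loss_w = 1) {
  d <- z - x
  list(loss = loss_w * mean(d * d), dz = loss_w * 2 * d / length(d))
}

# Convert a windows-by-samples matrix (n x L) to engine layout ((n*L) x 1).
as_engine_batch <- function(X) {
  n <- nrow(X)
  L <- ncol(X)
  dim(X) <- c(n * L, 1L)
  X
}
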