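# CNN classifier in base R over BLAS matrix products.
#
# Architecture: two blocks of [3x3 conv (64 filters, stride 1, same
# padding) -> batch normalization -> ReLU], no pooling (the input is only
# 16 x 20), flattened features into the ReLU fully-connected head.
# Convolution is computed as a sum of nine shifted matrix products over a
# zero-padded plane; feature maps live in matrices of shape
# channels x (positions * batch) with per-sample blocks contiguous.

CNN_H <- 16
CNN_W <- 20

# Index geometry for a given batch size (cached): positions of the
# unpadded plane inside the padded one, and of each of the nine 3x3
# shifts, replicated across sample blocks.
conv_geometry <- local({
  cache <- list()
  function(batch) {
    key <- as.character(batch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- CNN_H + 2; wp <- CNN_W + 2
    pos <- function(rows, cols) {
      as.vector(outer(rows, (cols - 1) * hp, `+`))
    }
    blocks <- (seq_len(batch) - 1) * (hp * wp)
    expand <- function(p) as.vector(outer(p, blocks, `+`))
    inner <- expand(pos(2:(CNN_H + 1), 2:(CNN_W + 1)))
    offs <- vector("list", 9)
    o <- 0
    for (dj in 0:2) for (di in 0:2) {
      o <- o + 1
      offs[[o]] <- expand(pos((1:CNN_H) + di, (1:CNN_W) + dj))
    }
    g <- list(inner = inner, offs = offs, pad_cols = hp * wp * batch)
    cache[[key]] <<- g
    g
  }
})

#' Initialize parameters of the CNN classifier
#'
#' @param seed integer seed for the draws.
#' @param filters convolutional filters per layer (64).
#' @param fc width of the fully-connected hidden layer (32).
#' @return named list of parameters, including batch-norm scale/shift and
#'   running statistics for inference.
#' @export
init_cnn_params <- function(seed = 1, filters = 64, fc = 32) {
  set.seed(seed)
  n_feat <- filters * CNN_H * CNN_W
  list(K1 = glorot(filters, 9), b1 = numeric(filters),
       g1 = rep(1, filters), be1 = numeric(filters),
       rm1 = numeric(filters), rv1 = rep(1, filters),
       K2 = glorot(filters, filters * 9), b2 = numeric(filters),
       g2 = rep(1, filters), be2 = numeric(filters),
       rm2 = numeric(filters), rv2 = rep(1, filters),
       Wf = glorot(fc, n_feat), bf = numeric(fc),
       Wo = glorot(2, fc), bo = numeric(2))
}

conv_pad <- function(input, geom) {
  pad <- matrix(0, nrow(input), geom$pad_cols)
  pad[, geom$inner] <- input
  pad
}

conv_apply <- function(pad, K, b, geom) {
  cin <- nrow(pad)
  out <- matrix(b, nrow(K), length(geom$offs[[1]]))
  for (o in 1:9) {
    Ko <- K[, ((o - 1) * cin + 1):(o * cin), drop = FALSE]
    out <- out + Ko %*% pad[, geom$offs[[o]], drop = FALSE]
  }
  out
}

conv_grads <- function(pad, dout, K, geom, want_dinput) {
  cin <- nrow(pad)
  dK <- matrix(0, nrow(K), ncol(K))
  dpad <- if (want_dinput) matrix(0, cin, ncol(pad)) else NULL
  for (o in 1:9) {
    sub <- pad[, geom$offs[[o]], drop = FALSE]
    dK[, ((o - 1) * cin + 1):(o * cin)] <- tcrossprod(dout, sub)
    if (want_dinput) {
      Ko <- K[, ((o - 1) * cin + 1):(o * cin), drop = FALSE]
      dpad[, geom$offs[[o]]] <- dpad[, geom$offs[[o]], drop = FALSE] +
        crossprod(Ko, dout)
    }
  }
  list(dK = dK, db = rowSums(dout),
       dinput = if (want_dinput) dpad[, geom$inner, drop = FALSE])
}

BN_EPS <- 1e-5

bn_forward <- function(A, g, be, training, rm, rv) {
  if (training) {
    mu <- rowMeans(A)
    va <- rowMeans((A - mu)^2)
  } else {
    mu <- rm; va <- rv
  }
  inv <- 1 / sqrt(va + BN_EPS)
  ahat <- (A - mu) * inv
  list(out = g * ahat + be, ahat = ahat, inv = inv, mu = mu, va = va)
}

bn_backward <- function(dout, fw, g) {
  m <- ncol(dout)
  dahat <- dout * g
  dg <- rowSums(dout * fw$ahat)
  dbe <- rowSums(dout)
  # standard batch-norm gradient with per-row statistics
  dA <- (dahat - rowMeans(dahat) - fw$ahat * rowMeans(dahat * fw$ahat)) * fw$inv
  list(dA = dA, dg = dg, dbe = dbe)
}

# Forward pass; returns probabilities and, when `keep` is TRUE, the
# intermediate activations needed for the backward pass.
cnn_forward_pass <- function(params, xflat, cols, training, keep = FALSE) {
  B <- length(cols)
  geom <- conv_geometry(B)
  input <- matrix(xflat[, cols], nrow = 1)   # 1 x (320*B), blocks contiguous
  pad1 <- conv_pad(input, geom)
  A1 <- conv_apply(pad1, params$K1, params$b1, geom)
  f1 <- bn_forward(A1, params$g1, params$be1, training, params$rm1, params$rv1)
  R1 <- pmax(f1$out, 0)
  pad2 <- conv_pad(R1, geom)
  A2 <- conv_apply(pad2, params$K2, params$b2, geom)
  f2 <- bn_forward(A2, params$g2, params$be2, training, params$rm2, params$rv2)
  R2 <- pmax(f2$out, 0)
  feat <- matrix(R2, nrow(R2) * CNN_H * CNN_W, B)
  hf <- pmax(params$Wf %*% feat + params$bf, 0)
  logits <- params$Wo %*% hf + params$bo
  logits <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(logits)
  probs <- sweep(e, 2, colSums(e), "/")
  if (!keep) return(list(probs = probs))
  list(probs = probs, geom = geom, pad1 = pad1, f1 = f1, R1 = R1,
       pad2 = pad2, f2 = f2, R2 = R2, feat = feat, hf = hf)
}

cnn_backward_pass <- function(params, fw, dlogits) {
  dWo <- tcrossprod(dlogits, fw$hf)
  dbo <- rowSums(dlogits)
  dhf <- crossprod(params$Wo, dlogits)
  dhf[fw$hf <= 0] <- 0
  dWf <- tcrossprod(dhf, fw$feat)
  dbf <- rowSums(dhf)
  dfeat <- crossprod(params$Wf, dhf)
  dR2 <- matrix(dfeat, nrow(fw$R2), ncol(fw$R2))
  dR2[fw$f2$out <= 0] <- 0
  b2g <- bn_backward(dR2, fw$f2, params$g2)
  c2g <- conv_grads(fw$pad2, b2g$dA, params$K2, fw$geom, want_dinput = TRUE)
  dR1 <- c2g$dinput
  dR1[fw$f1$out <= 0] <- 0
  b1g <- bn_backward(dR1, fw$f1, params$g1)
  c1g <- conv_grads(fw$pad1, b1g$dA, params$K1, fw$geom, want_dinput = FALSE)
  list(K1 = c1g$dK, b1 = c1g$db, g1 = b1g$dg, be1 = b1g$dbe,
       K2 = c2g$dK, b2 = c2g$db, g2 = b2g$dg, be2 = b2g$dbe,
       Wf = dWf, bf = dbf, Wo = dWo, bo = dbo)
}

cnn_forward <- function(params, xflat, batch_size = 256) {
  n <- ncol(xflat)
  out <- matrix(0, 2, n)
  for (at in seq(1, n, by = batch_size)) {
    cols <- at:min(at + batch_size - 1, n)
    out[, cols] <- cnn_forward_pass(params, xflat, cols,
                                    training = FALSE)$probs
  }
  out
}

adam_init <- function(params, trainable) {
  list(m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(state$m)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

binary_rates <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  fp <- sum(pred == 1 & truth == 0); tn <- sum(pred == 0 & truth == 0)
  sens <- if (tp + fn) tp / (tp + fn) else NaN
  spec <- if (fp + tn) tn / (fp + tn) else NaN
  c(acc = (tp + tn) / length(truth), sens = sens, spec = spec,
    ba = (sens + spec) / 2)
}

cnn_train <- function(params, xtrain, ytrain, xval, yval, shuffle,
                      class_wt, lr, batch_size, select_metric) {
  trainable <- c("K1", "b1", "g1", "be1", "K2", "b2", "g2", "be2",
                 "Wf", "bf", "Wo", "bo")
  state <- adam_init(params, trainable)
  epochs <- ncol(shuffle)
  n_train <- length(ytrain)
  history <- matrix(0, epochs, 4)
  best <- params; best_metric <- -1; best_epoch <- 0
  momentum <- 0.9

  for (e in seq_len(epochs)) {
    loss_sum <- 0; correct <- 0
    for (at in seq(1, n_train, by = batch_size)) {
      take <- at:min(at + batch_size - 1, n_train)
      cols <- shuffle[take, e] + 1L
      yb <- ytrain[cols]
      B <- length(cols)
      fw <- cnn_forward_pass(params, xtrain, cols, training = TRUE,
                             keep = TRUE)
      w <- class_wt[yb + 1L]
      p_true <- fw$probs[cbind(yb + 1L, seq_len(B))]
      loss_sum <- loss_sum + sum(-w * log(pmax(p_true, 1e-12)))
      correct <- correct + sum((fw$probs[2, ] >= 0.5) == (yb == 1))
      dlogits <- fw$probs
      dlogits[cbind(yb + 1L, seq_len(B))] <-
        dlogits[cbind(yb + 1L, seq_len(B))] - 1
      dlogits <- sweep(dlogits, 2, w / B, "*")
      grads <- cnn_backward_pass(params, fw, dlogits)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      # running statistics for inference-mode batch norm
      params$rm1 <- momentum * params$rm1 + (1 - momentum) * fw$f1$mu
      params$rv1 <- momentum * params$rv1 + (1 - momentum) * fw$f1$va
      params$rm2 <- momentum * params$rm2 + (1 - momentum) * fw$f2$mu
      params$rv2 <- momentum * params$rv2 + (1 - momentum) * fw$f2$va
    }
    train_loss <- loss_sum / n_train
    if (!is.finite(train_loss))
      stop("training diverged: non-finite loss at epoch ", e)
    pv <- cnn_forward(params, xval)
    rates <- binary_rates(as.integer(pv[2, ] >= 0.5), yval)
    history[e, ] <- c(train_loss, correct / n_train, rates["acc"],
                      rates["ba"])
    metric <- if (select_metric == "ba") rates["ba"] else rates["acc"]
    if (is.finite(metric) && metric > best_metric) {
      best_metric <- metric; best <- params; best_epoch <- e
    }
  }
  list(params = best, history = history, best_epoch = best_epoch,
       best_metric = best_metric)
}
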