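# Cascade feedforward regressor: a stack of narrow tanh blocks with dense
# skip connectivity. Block i receives [inputs, h_1, ..., h_{i-1}]; a linear
# head reads the inputs together with every block output, so a purely
# linear target is representable by the head alone. Trained full-batch by
# Adam with early stopping on an internal validation split.

cascade_defaults <- function() {
  list(blocks = 12L, width = 16L, lr = 0.01, epochs = 400L,
       patience = 25L, val_frac = 0.15, l2 = 0.02)
}

cascade_init <- function(p, blocks, width) {
  W <- vector("list", blocks); b <- vector("list", blocks)
  d <- p
  for (i in seq_len(blocks)) {
    s <- sqrt(6 / (d + width))
    W[[i]] <- matrix(runif(width * d, -s, s), width, d)
    b[[i]] <- rep(0, width)
    d <- d + width
  }
  s <- sqrt(6 / (d + 1))
  list(W = W, b = b, w_out = runif(d, -s, s), b_out = 0)
}

cascade_forward <- function(par, X, keep = FALSE) {
  C <- X
  H <- if (keep) vector("list", length(par$W)) else NULL
  Cs <- if (keep) vector("list", length(par$W)) else NULL
  for (i in seq_along(par$W)) {
    if (keep) Cs[[i]] <- C
    A <- tcrossprod(C, par$W[[i]])
    A <- sweep(A, 2, par$b[[i]], `+`)
    Hi <- tanh(A)
    if (keep) H[[i]] <- Hi
    C <- cbind(C, Hi)
  }
  yhat <- drop(C %*% par$w_out) + par$b_out
  if (keep) list(yhat = yhat, H = H, Cs = Cs, C_final = C) else yhat
}

cascade_grad <- function(par, X, y, l2 = 0) {
  fw <- cascade_forward(par, X, keep = TRUE)
  n <- nrow(X)
  r <- (fw$yhat - y) / n                      # d(mean 0.5 r^2)/d yhat
  g <- list(W = vector("list", length(par$W)),
            b = vector("list", length(par$W)),
            w_out = drop(crossprod(fw$C_final, r)),
            b_out = sum(r))
  gC <- outer(r, par$w_out)                   # n x dim(C_final)
  for (i in rev(seq_along(par$W))) {
    d_prev <- ncol(fw$Cs[[i]])
    gH <- gC[, (d_prev + 1):ncol(gC), drop = FALSE]
    gA <- gH * (1 - fw$H[[i]]^2)
    g$W[[i]] <- crossprod(gA, fw$Cs[[i]])
    g$b[[i]] <- colSums(gA)
    gC <- gC[, seq_len(d_prev), drop = FALSE] + gA %*% par$W[[i]]
  }
  if (l2 > 0) {  # weight decay on weights, not biases
    for (i in seq_along(par$W)) g$W[[i]] <- g$W[[i]] + l2 * par$W[[i]]
    g$w_out <- g$w_out + l2 * par$w_out
  }
  list(grad = g, loss = mean((fw$yhat - y)^2))
}

# flatten/unflatten so Adam state is a single vector
cascade_pack <- function(par) {
  unlist(list(W = lapply(par$W, as.numeric), b = par$b,
              w_out = par$w_out, b_out = par$b_out), use.names = FALSE)
}

cascade_unpack <- function(theta, skel) {
  out <- skel; k <- 0L
  for (i in seq_along(skel$W)) {
    len <- length(skel$W[[i]])
    out$W[[i]] <- matrix(theta[k + seq_len(len)], nrow(skel$W[[i]]))
    k <- k + len
  }
  for (i in seq_along(skel$b)) {
    len <- length(skel$b[[i]])
    out$b[[i]] <- theta[k + seq_len(len)]; k <- k + len
  }
  len <- length(skel$w_out)
  out$w_out <- theta[k + seq_len(len)]; k <- k + len
  out$b_out <- theta[k + 1L]
  out
}

cascade_train <- function(X, y, hyper = list()) {
  hp <- modifyList(cascade_defaults(), hyper)
  n <- nrow(X)
  # standardize target for optimisation stability
  y_center <- mean(y); y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale <= 0)
    stop_validation("target (age) is constant; cannot train")
  ys <- (y - y_center) / y_scale

  n_val <- max(2L, round(hp$val_frac * n))
  idx <- sample.int(n)
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]

  par <- cascade_init(ncol(X), hp$blocks, hp$width)
  theta <- cascade_pack(par)
  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(theta = theta, val = Inf, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(hp$epochs)) {
    par <- cascade_unpack(theta, par)
    gr <- cascade_grad(par, X[trn, , drop = FALSE], ys[trn], l2 = hp$l2)
    gvec <- cascade_pack(gr$grad)
    m <- beta1 * m + (1 - beta1) * gvec
    v <- beta2 * v + (1 - beta2) * gvec^2
    mhat <- m / (1 - beta1^epoch)
    vhat <- v / (1 - beta2^epoch)
    theta <- theta - hp$lr * mhat / (sqrt(vhat) + eps)
    val_pred <- cascade_forward(cascade_unpack(theta, par),
                                X[val, , drop = FALSE])
    val_mse <- mean((val_pred - ys[val])^2)
    if (val_mse < best$val - 1e-9) {
      best <- list(theta = theta, val = val_mse, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  list(par = cascade_unpack(best$theta, par), y_center = y_center,
       y_scale = y_scale, hyper = hp, best_epoch = best$epoch,
       val_mse = best$val)
}

cascade_predict <- function(fit, X) {
  cascade_forward(fit$par, X) * fit$y_scale + fit$y_center
}
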