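# Recurrent network primitives.
#
# Everything here operates on batched sequences represented as lists of
# per-timestep matrices (batch x features).  Gate layout in all 4h-wide
# LSTM matrices is [input | forget | candidate | output].  The forward
# pass caches gate activations so the analytic backward pass
# (backpropagation through time) can run without recomputation; the
# gradients are verified against central finite differences in the test
# suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform initialization in +/- 1/sqrt(fan-in); forget-gate bias 1 (the
# standard trick that keeps memory open early in training).  Draws from
# the current RNG stream.
lstm_init <- function(input_dim, h) {
  rw <- 1 / sqrt(input_dim)
  ru <- 1 / sqrt(h)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(W = matrix(stats::runif(input_dim * 4 * h, -rw, rw), input_dim, 4 * h),
       U = matrix(stats::runif(h * 4 * h, -ru, ru), h, 4 * h),
       b = b)
}

dense_init <- function(input_dim, out_dim) {
  r <- 1 / sqrt(input_dim)
  list(W = matrix(stats::runif(input_dim * out_dim, -r, r), input_dim, out_dim),
       b = rep(0, out_dim))
}

# Forward pass over a sequence.  X: list of T (batch x input_dim)
# matrices in scan order (caller reverses the list for a backward
# direction).  init: optional list(c, h) of initial states.
lstm_forward <- function(X, p, init = NULL) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  h <- nrow(p$U)
  ii <- seq_len(h); ff <- h + ii; gg <- 2 * h + ii; oo <- 3 * h + ii
  bmat <- matrix(p$b, B, 4 * h, byrow = TRUE)
  zero <- matrix(0, B, h)
  c_prev <- if (is.null(init)) zero else init$c
  h_prev <- if (is.null(init)) zero else init$h
  H <- vector("list", Tn)
  G <- vector("list", Tn)
  C <- vector("list", Tn)
  tC <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Z <- X[[t]] %*% p$W + h_prev %*% p$U + bmat
    Z[, ii] <- sigmoid(Z[, ii])
    Z[, ff] <- sigmoid(Z[, ff])
    Z[, gg] <- tanh(Z[, gg])
    Z[, oo] <- sigmoid(Z[, oo])
    c_cur <- Z[, ff, drop = FALSE] * c_prev + Z[, ii, drop = FALSE] * Z[, gg, drop = FALSE]
    tc <- tanh(c_cur)
    h_cur <- Z[, oo, drop = FALSE] * tc
    G[[t]] <- Z; C[[t]] <- c_cur; tC[[t]] <- tc; H[[t]] <- h_cur
    c_prev <- c_cur; h_prev <- h_cur
  }
  list(H = H, final = list(c = c_prev, h = h_prev),
       X = X, G = G, C = C, tC = tC, init = init)
}

# Backward pass.  fwd: output of lstm_forward.  dH: list of gradients on
# each output (NULL entries allowed), dfinal: gradient on the final
# (c, h) state.  Returns parameter gradients, dX (when need_dx) and the
# gradient on the initial state (for state hand-off chains).
lstm_backward <- function(p, fwd, dH = NULL, dfinal = NULL, need_dx = FALSE) {
  Tn <- length(fwd$X)
  B <- nrow(fwd$X[[1]])
  h <- nrow(p$U)
  ii <- seq_len(h); ff <- h + ii; gg <- 2 * h + ii; oo <- 3 * h + ii
  zero <- matrix(0, B, h)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, h, 4 * h)
  db <- rep(0, 4 * h)
  dX <- if (need_dx) vector("list", Tn) else NULL
  dh_next <- if (is.null(dfinal)) zero else dfinal$h
  dc_next <- if (is.null(dfinal)) zero else dfinal$c
  init_c <- if (is.null(fwd$init)) zero else fwd$init$c
  init_h <- if (is.null(fwd$init)) zero else fwd$init$h
  for (t in rev(seq_len(Tn))) {
    dh <- dh_next
    if (!is.null(dH) && !is.null(dH[[t]])) dh <- dh + dH[[t]]
    G <- fwd$G[[t]]
    i <- G[, ii, drop = FALSE]; f <- G[, ff, drop = FALSE]
    g <- G[, gg, drop = FALSE]; o <- G[, oo, drop = FALSE]
    tc <- fwd$tC[[t]]
    c_prev <- if (t > 1) fwd$C[[t - 1]] else init_c
    h_prev <- if (t > 1) fwd$H[[t - 1]] else init_h
    dc <- dc_next + dh * o * (1 - tc^2)
    dZ <- cbind(dc * g * i * (1 - i),
                dc * c_prev * f * (1 - f),
                dc * i * (1 - g^2),
                dh * tc * o * (1 - o))
    dW <- dW + crossprod(fwd$X[[t]], dZ)
    dU <- dU + crossprod(h_prev, dZ)
    db <- db + colSums(dZ)
    if (need_dx) dX[[t]] <- tcrossprod(dZ, p$W)
    dh_next <- tcrossprod(dZ, p$U)
    dc_next <- dc * f
  }
  list(dW = dW, dU = dU, db = db, dX = dX,
       dinit = list(c = dc_next, h = dh_next))
}

# ---- full encoder-decoder model ------------------------------------------

# Initialize all parameters from the current RNG stream.
uvnet_init_params <- function(n_features, control) {
  h1 <- control$encoder_hidden[1]
  h2 <- control$encoder_hidden[2]
  list(enc1f = lstm_init(n_features, h1),
       enc1b = lstm_init(n_features, h1),
       enc2 = lstm_init(2 * h1, h2),
       dec = lstm_init(n_features, h2),
       d1 = dense_init(h2, control$dense_hidden),
       d2 = dense_init(control$dense_hidden, 1))
}

# Draw inverted-dropout masks for a training forward pass (one pair of
# masks per decoder timestep) from the current RNG stream.
draw_dropout_masks <- function(B, n_steps, h2, dh, p) {
  keep <- 1 - p
  draw <- function(n, m) {
    matrix((stats::runif(n * m) < keep) / keep, n, m)
  }
  list(h = lapply(seq_len(n_steps), function(t) draw(B, h2)),
       a1 = lapply(seq_len(n_steps), function(t) draw(B, dh)))
}

# Full forward pass.  batch: output of stack_windows (lists A, B).
# masks: dropout masks (training mode) or NULL (inference).  Returns
# Yhat (batch x n_slots) plus caches for the backward pass.
nnet_forward <- function(params, batch, control, masks = NULL,
                         keep_cache = FALSE) {
  enc1f <- lstm_forward(batch$A, params$enc1f)
  enc1b <- lstm_forward(rev(batch$A), params$enc1b)
  H1 <- Map(cbind, enc1f$H, rev(enc1b$H))
  enc2 <- lstm_forward(H1, params$enc2)
  B <- nrow(batch$A[[1]])
  h2 <- control$encoder_hidden[2]
  dec_init <- list(c = enc2$final$c,
                   h = if (control$init_hidden) enc2$final$h
                       else matrix(0, B, h2))
  dec <- lstm_forward(batch$B, params$dec, init = dec_init)
  S <- length(batch$B)
  b1mat <- matrix(params$d1$b, B, length(params$d1$b), byrow = TRUE)
  Yhat <- matrix(0, B, S)
  hd_post <- a1_pre <- a1_post <- vector("list", S)
  for (t in seq_len(S)) {
    hd <- dec$H[[t]]
    if (!is.null(masks)) hd <- hd * masks$h[[t]]
    a1 <- sigmoid(hd %*% params$d1$W + b1mat)
    a1p <- if (!is.null(masks)) a1 * masks$a1[[t]] else a1
    Yhat[, t] <- sigmoid(a1p %*% params$d2$W + params$d2$b)
    if (keep_cache) {
      hd_post[[t]] <- hd; a1_pre[[t]] <- a1; a1_post[[t]] <- a1p
    }
  }
  out <- list(Yhat = Yhat)
  if (keep_cache) {
    out <- c(out, list(enc1f = enc1f, enc1b = enc1b, enc2 = enc2, dec = dec,
                       hd_post = hd_post, a1_pre = a1_pre, a1_post = a1_post,
                       masks = masks))
  }
  out
}

# Backward pass for the quantile loss.  fwd must be a cached forward.
# Subgradient at the kink uses the q side.
nnet_backward <- function(params, fwd, Y, q, control) {
  Yhat <- fwd$Yhat
  B <- nrow(Yhat); S <- ncol(Yhat)
  e <- Yhat - Y
  dY <- (q - (e < 0)) / (B * S)
  dh1 <- dim(params$d1$W)
  dW1 <- matrix(0, dh1[1], dh1[2]); db1 <- rep(0, dh1[2])
  dW2 <- matrix(0, nrow(params$d2$W), 1); db2 <- 0
  dH_dec <- vector("list", S)
  for (t in seq_len(S)) {
    yh <- Yhat[, t]
    dz2 <- matrix(dY[, t] * yh * (1 - yh), B, 1)
    dW2 <- dW2 + crossprod(fwd$a1_post[[t]], dz2)
    db2 <- db2 + sum(dz2)
    da1 <- tcrossprod(dz2, params$d2$W)
    if (!is.null(fwd$masks)) da1 <- da1 * fwd$masks$a1[[t]]
    a1 <- fwd$a1_pre[[t]]
    dz1 <- da1 * a1 * (1 - a1)
    dW1 <- dW1 + crossprod(fwd$hd_post[[t]], dz1)
    db1 <- db1 + colSums(dz1)
    dhd <- tcrossprod(dz1, params$d1$W)
    if (!is.null(fwd$masks)) dhd <- dhd * fwd$masks$h[[t]]
    dH_dec[[t]] <- dhd
  }
  dec_b <- lstm_backward(params$dec, fwd$dec, dH = dH_dec)
  h2 <- control$encoder_hidden[2]
  denc2_final <- list(c = dec_b$dinit$c,
                      h = if (control$init_hidden) dec_b$dinit$h
                          else matrix(0, nrow(dec_b$dinit$h), h2))
  enc2_b <- lstm_backward(params$enc2, fwd$enc2, dfinal = denc2_final,
                          need_dx = TRUE)
  h1 <- control$encoder_hidden[1]
  dHf <- lapply(enc2_b$dX, function(m) m[, seq_len(h1), drop = FALSE])
  dHb <- rev(lapply(enc2_b$dX, function(m) m[, h1 + seq_len(h1), drop = FALSE]))
  enc1f_b <- lstm_backward(params$enc1f, fwd$enc1f, dH = dHf)
  enc1b_b <- lstm_backward(params$enc1b, fwd$enc1b, dH = dHb)
  pick <- function(b) list(W = b$dW, U = b$dU, b = b$db)
  list(enc1f = pick(enc1f_b), enc1b = pick(enc1b_b), enc2 = pick(enc2_b),
       dec = pick(dec_b),
       d1 = list(W = dW1, b = db1), d2 = list(W = dW2, b = db2))
}

# ---- parameter vector helpers --------------------------------------------

flatten_params <- function(p) {
  unlist(p, use.names = TRUE)
}

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (layer in names(template)) {
    for (part in names(template[[layer]])) {
      n <- length(template[[layer]][[part]])
      piece <- flat[pos + seq_len(n)]
      attributes(piece) <- NULL
      dim(piece) <- dim(template[[layer]][[part]])
      out[[layer]][[part]] <- piece
      pos <- pos + n
    }
  }
  out
}
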