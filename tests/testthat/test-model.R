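test_that("quantile loss matches direct evaluation of the formula", {
  expect_equal(quantile_loss(0, 3, 0.33), 0.99)    # over-prediction: q*e
  expect_equal(quantile_loss(0, -3, 0.33), 2.01)   # under-prediction: (q-1)*e
  expect_equal(quantile_loss(c(1, 2), c(1, 2), 0.33), 0)
  # under-prediction penalised (1-q)/q times more
  expect_equal(quantile_loss(0, -3, 0.33) / quantile_loss(0, 3, 0.33),
               (1 - 0.33) / 0.33)
  set.seed(21)
  y <- rnorm(50); yh <- rnorm(50); q <- 0.7
  direct <- mean(pmax(q * (yh - y), (q - 1) * (yh - y)))
  expect_equal(quantile_loss(y, yh, q), direct)
})

test_that("quantile loss obeys the reflection identity and half-MAE case", {
  set.seed(22)
  for (i in 1:5) {
    y <- rnorm(30); yh <- rnorm(30); q <- runif(1, 0.05, 0.95)
    expect_equal(quantile_loss(y, yh, q), quantile_loss(yh, y, 1 - q))
    expect_equal(quantile_loss(y, yh, 0.5), mean(abs(yh - y)) / 2)
  }
})

test_that("with q < 0.5 over-forecasting costs less than under-forecasting", {
  y <- runif(20, 1, 2)
  for (delta in c(0.1, 0.5)) {
    expect_lt(quantile_loss(y, y + delta, 0.33),
              quantile_loss(y, y - delta, 0.33))
  }
})

test_that("quantile loss is convex along random directions", {
  set.seed(23)
  y <- rnorm(20)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20); lam <- runif(1)
    mid <- lam * a + (1 - lam) * b
    expect_lte(quantile_loss(y, mid, 0.33),
               lam * quantile_loss(y, a, 0.33) +
                 (1 - lam) * quantile_loss(y, b, 0.33) + 1e-12)
  }
})

make_tiny_batch <- function(B = 2, Tn = 6, S = 4, nf = 3, seed = 99) {
  set.seed(seed)
  list(A = lapply(seq_len(Tn), function(t) matrix(runif(B * nf), B, nf)),
       B = lapply(seq_len(S), function(t) matrix(runif(B * nf), B, nf)),
       Y = matrix(runif(B * S, 0.2, 0.8), B, S),
       n = B, n_slots = S, n_steps = Tn)
}

test_that("analytic gradients agree with central finite differences", {
  ctrl <- uvnet_control(encoder_hidden = c(3, 4), dense_hidden = 5,
                        dropout = 0, smoothing_window = 1,
                        smoothing_polyorder = 0)
  set.seed(31)
  params <- uvcast:::uvnet_init_params(3, ctrl)
  batch <- make_tiny_batch()
  q <- 0.33
  fwd <- uvcast:::nnet_forward(params, batch, ctrl, keep_cache = TRUE)
  ga <- uvcast:::flatten_params(
    uvcast:::nnet_backward(params, fwd, batch$Y, q, ctrl))
  theta <- uvcast:::flatten_params(params)
  lossf <- function(th) {
    p <- uvcast:::unflatten_params(th, params)
    quantile_loss(batch$Y, uvcast:::nnet_forward(p, batch, ctrl)$Yhat, q)
  }
  idx <- unique(round(seq(1, length(theta), length.out = 60)))
  eps <- 1e-6
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (lossf(tp) - lossf(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("inference is deterministic and outputs stay in (0,1)", {
  ctrl <- uvnet_control(encoder_hidden = c(3, 4), dense_hidden = 5,
                        dropout = 0.2)
  set.seed(32)
  params <- uvcast:::uvnet_init_params(3, ctrl)
  batch <- make_tiny_batch(B = 3)
  y1 <- uvcast:::nnet_forward(params, batch, ctrl)$Yhat
  y2 <- uvcast:::nnet_forward(params, batch, ctrl)$Yhat
  expect_identical(y1, y2)
  expect_true(all(y1 > 0 & y1 < 1))
})

test_that("doubling the input length leaves output dimensions unchanged", {
  ctrl <- uvnet_control(encoder_hidden = c(3, 4), dense_hidden = 5,
                        dropout = 0)
  set.seed(33)
  params <- uvcast:::uvnet_init_params(3, ctrl)
  short <- make_tiny_batch(Tn = 6)
  long <- make_tiny_batch(Tn = 12)
  ys <- uvcast:::nnet_forward(params, short, ctrl)$Yhat
  yl <- uvcast:::nnet_forward(params, long, ctrl)$Yhat
  expect_equal(dim(ys), dim(yl))
})

test_that("zero weights and zero input give a zero cell state", {
  ctrl <- uvnet_control(encoder_hidden = c(3, 4), dense_hidden = 5,
                        dropout = 0)
  set.seed(34)
  params <- uvcast:::uvnet_init_params(3, ctrl)
  zero_lstm <- function(p) {
    p$W[] <- 0; p$U[] <- 0; p$b[] <- 0; p
  }
  p0 <- lapply(params[c("enc1f", "enc1b", "enc2", "dec")], zero_lstm)
  X <- lapply(1:5, function(t) matrix(0, 2, 3))
  fwd <- uvcast:::lstm_forward(X, p0$enc1f)
  # with all gate pre-activations 0 the candidate tanh(0)=0, so the cell
  # state stays at the origin fixed point
  expect_equal(fwd$final$c, matrix(0, 2, 3))
})

test_that("training-mode dropout equals a manual Bernoulli-mask oracle", {
  ctrl <- uvnet_control(encoder_hidden = c(3, 4), dense_hidden = 5,
                        dropout = 0.4)
  set.seed(35)
  params <- uvcast:::uvnet_init_params(3, ctrl)
  batch <- make_tiny_batch(B = 2, S = 3)
  set.seed(77)
  masks <- uvcast:::draw_dropout_masks(2, 3, 4, 5, 0.4)
  yhat <- uvcast:::nnet_forward(params, batch, ctrl, masks = masks)$Yhat
  # oracle: replay the forward pass applying the same masks by hand
  enc1f <- uvcast:::lstm_forward(batch$A, params$enc1f)
  enc1b <- uvcast:::lstm_forward(rev(batch$A), params$enc1b)
  H1 <- Map(cbind, enc1f$H, rev(enc1b$H))
  enc2 <- uvcast:::lstm_forward(H1, params$enc2)
  dec <- uvcast:::lstm_forward(batch$B, params$dec,
                               init = list(c = enc2$final$c,
                                           h = enc2$final$h))
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in 1:3) {
    hd <- dec$H[[t]] * masks$h[[t]]
    a1 <- sig(hd %*% params$d1$W +
                matrix(params$d1$b, 2, 5, byrow = TRUE)) * masks$a1[[t]]
    yo <- sig(a1 %*% params$d2$W + params$d2$b)
    expect_equal(yhat[, t], as.numeric(yo))
  }
})

test_that("the learning-rate schedule decays linearly per epoch", {
  tr <- uvnet_training()
  expect_equal(tr$lr_init - 2000 * tr$lr_decay, 3e-4)
  expect_error(uvnet_training(lr_init = 1e-4, lr_decay = 1e-7,
                              epochs = 2000), "positive")
})

test_that("identical seeds reproduce identical fits", {
  sim <- clean_sim(n_years = 2, seed = 41)
  targets <- seq(as.Date("2012-03-01"), by = "day", length.out = 6)
  tr <- uvnet_training(epochs = 3, batch_size = 4)
  m1 <- uvnet(sim$series, K = 3, targets = targets,
              control = tiny_control(dropout = 0.2), training = tr, seed = 5)
  m2 <- uvnet(sim$series, K = 3, targets = targets,
              control = tiny_control(dropout = 0.2), training = tr, seed = 5)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$loss_log, m2$loss_log)
  m3 <- uvnet(sim$series, K = 3, targets = targets,
              control = tiny_control(dropout = 0.2), training = tr, seed = 6)
  expect_false(identical(coef(m1), coef(m3)))
})

test_that("checkpoints round-trip through save and load", {
  sim <- clean_sim(n_years = 2, seed = 42)
  targets <- seq(as.Date("2012-03-01"), by = "day", length.out = 4)
  m <- uvnet(sim$series, K = 2, targets = targets,
             control = tiny_control(),
             training = uvnet_training(epochs = 2, batch_size = 4), seed = 1)
  tf <- withr::local_tempfile(fileext = ".rds")
  uvnet_save(m, tf)
  back <- uvnet_load(tf)
  expect_identical(coef(back), coef(m))
  expect_equal(back$scale, m$scale)
  saveRDS(list(format = "other"), tf)
  expect_error(uvnet_load(tf), "checkpoint")
})

test_that("model methods expose the fit coherently", {
  sim <- clean_sim(n_years = 2, seed = 43)
  targets <- seq(as.Date("2012-03-01"), by = "day", length.out = 5)
  m <- uvnet(sim$series, K = 2, targets = targets,
             control = tiny_control(),
             training = uvnet_training(epochs = 2, batch_size = 8), seed = 2)
  expect_output(print(m), "forecaster")
  sm <- summary(m)
  expect_equal(sm$n_parameters, length(coef(m)))
  expect_equal(dim(residuals(m)), dim(fitted(m)))
  expect_equal(residuals(m), m$target - fitted(m), ignore_attr = TRUE)
  expect_true(all(fitted(m) >= 0 & fitted(m) <= m$scale))
  tf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tf); plot(m); grDevices::dev.off()
  expect_true(file.exists(tf))
})
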