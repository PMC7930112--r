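#' Quantile (pinball) loss
#'
#' `mean(max(q * (yhat - y), (q - 1) * (yhat - y)))`.  With `q < 0.5`
#' under-prediction is penalised `(1 - q) / q` times more than
#' over-prediction of the same size; the forecaster trains with
#' `q = 0.33` so that, in a heliotherapy setting, it errs towards
#' over-estimating irradiance (an under-estimate would prescribe too long
#' a sunbathing session and risk sunburn).
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @param q Quantile in (0, 1).
#' @return Non-negative scalar; 0 iff `yhat == y` elementwise.
#' @export
quantile_loss <- function(y, yhat, q = 0.33) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' must have equal length")
  if (length(y) == 0) stop("'y' must be non-empty")
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  e <- yhat - y
  mean(pmax(q * e, (q - 1) * e))
}

#' Forecaster architecture settings
#'
#' @param encoder_hidden Two encoder layer widths: the first layer is a
#'   bidirectional LSTM of this width per direction, the second a
#'   unidirectional LSTM whose final cell state is handed to the decoder.
#' @param dense_hidden Width of the first of the two sigmoid dense layers
#'   that map each decoder timestep to an output value.
#' @param dropout Dropout probability applied (training mode only) to the
#'   decoder LSTM output and to the first dense layer's activations.
#' @param quantile Quantile `q` of the training loss (see
#'   [quantile_loss()]).
#' @param init_hidden Also hand the encoder's final hidden state to the
#'   decoder (the cell-state hand-off is always performed).
#' @param smoothing_window,smoothing_polyorder Savitzky-Golay input
#'   denoising parameters (see [smooth_profile()]).
#' @return A list of class `uvnet_control`.
#' @export
uvnet_control <- function(encoder_hidden = c(128, 256), dense_hidden = 160,
                          dropout = 0.2, quantile = 0.33, init_hidden = TRUE,
                          smoothing_window = 11, smoothing_polyorder = 3) {
  if (length(encoder_hidden) != 2 || any(encoder_hidden < 1)) {
    stop("'encoder_hidden' must give two positive layer widths")
  }
  if (dense_hidden < 1) stop("'dense_hidden' must be positive")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must lie in [0, 1)")
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must lie in (0, 1)")
  structure(list(encoder_hidden = as.integer(encoder_hidden),
                 dense_hidden = as.integer(dense_hidden),
                 dropout = dropout, quantile = quantile,
                 init_hidden = isTRUE(init_hidden),
                 smoothing_window = smoothing_window,
                 smoothing_polyorder = smoothing_polyorder),
            class = "uvnet_control")
}

#' Optimisation settings
#'
#' ADAM with a linearly decaying learning rate: at epoch `e` the rate is
#' `lr_init - e * lr_decay` (defaults 5e-4 and 1e-7, so the rate after
#' 2000 epochs is 3e-4).
#'
#' @param lr_init Initial learning rate.
#' @param lr_decay Linear decay per epoch; `lr_init` must stay positive
#'   over the epoch budget.
#' @param epochs Number of passes over the training windows.
#' @param batch_size Minibatch size.
#' @return A list of class `uvnet_training`.
#' @export
uvnet_training <- function(lr_init = 5e-4, lr_decay = 1e-7, epochs = 2000,
                           batch_size = 256) {
  if (lr_decay < 0) stop("'lr_decay' must be non-negative")
  if (lr_init <= epochs * lr_decay) {
    stop("'lr_init' must exceed epochs * lr_decay (learning rate must stay positive)")
  }
  if (epochs < 1 || batch_size < 1) stop("'epochs' and 'batch_size' must be positive")
  structure(list(lr_init = lr_init, lr_decay = lr_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "uvnet_training")
}

# Evaluate and restore the global RNG state around seeded code.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

adam_state <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

slice_batch <- function(stacked, idx) {
  list(A = lapply(stacked$A, function(m) m[idx, , drop = FALSE]),
       B = lapply(stacked$B, function(m) m[idx, , drop = FALSE]),
       Y = stacked$Y[idx, , drop = FALSE],
       n = length(idx), n_slots = stacked$n_slots,
       n_steps = stacked$n_steps)
}

#' Fit the sequence-to-sequence UV forecaster
#'
#' Trains an encoder-decoder recurrent network that forecasts the next
#' day's weighted-irradiance profile at the grid resolution.  The encoder
#' (a bidirectional LSTM followed by a unidirectional LSTM) reads the
#' smoothed, normalized profiles of the `K` days before the forecast date
#' as one contiguous sequence and hands its final cell state to the
#' decoder; the decoder LSTM reads the previous year's same-date profile
#' and two sigmoid dense layers map each timestep to a forecast value in
#' (0, 1).  Training minimises the asymmetric quantile loss with ADAM
#' under a linearly decaying learning rate; when validation targets are
#' supplied the parameters with the best validation loss are retained.
#'
#' All randomness (initialisation, shuffling, dropout) flows from `seed`;
#' identical calls produce identical fits.
#'
#' @param series Training [uv_series()] (imputed; see [uv_impute()]).
#' @param K Number of past days fed to the encoder (7, 14 or 21 in the
#'   reference configuration).
#' @param targets Forecast dates to train on; defaults to every date with
#'   complete history in `series`.
#' @param val_series,val_targets Optional validation data.  The
#'   validation series should contain its own history days; windows are
#'   built from it with the training scale.
#' @param covariates Optional list of [uv_covariate()] input channels.
#' @param lead Forecast lead in days (1 = next day; larger values train
#'   the fixed-offset "forecast specific date" variant).
#' @param control A [uvnet_control()].
#' @param training A [uvnet_training()].
#' @param seed Integer seed controlling the whole run.
#' @param verbose Print a progress line every `verbose` epochs (0 = quiet).
#' @return An object of class `uvnet`; see [predict.uvnet()],
#'   [coef.uvnet()], [residuals.uvnet()], [plot.uvnet()].
#' @export
uvnet <- function(series, K = 14, targets = NULL, val_series = NULL,
                  val_targets = NULL, covariates = NULL, lead = 1,
                  control = uvnet_control(), training = uvnet_training(),
                  seed = 1, verbose = 0) {
  cl <- match.call()
  scale <- max(series$values, na.rm = TRUE)
  ws <- build_windows(series, K = K, targets = targets, lead = lead,
                      scale = scale, covariates = covariates,
                      smoothing_window = control$smoothing_window,
                      smoothing_polyorder = control$smoothing_polyorder)
  if (!length(ws$windows)) stop("no usable training windows")
  stacked <- stack_windows(ws)
  val_stacked <- NULL
  if (!is.null(val_series)) {
    vws <- build_windows(val_series, K = K, targets = val_targets,
                         lead = lead, scale = scale,
                         covariates = covariates,
                         cov_scales = ws$cov_scales,
                         smoothing_window = control$smoothing_window,
                         smoothing_polyorder = control$smoothing_polyorder)
    if (length(vws$windows)) val_stacked <- stack_windows(vws)
  }
  n_features <- length(ws$feature_names)
  q <- control$quantile
  tr <- training

  fit <- with_seed(seed, {
    params <- uvnet_init_params(n_features, control)
    template <- params
    theta <- flatten_params(params)
    st <- adam_state(length(theta))
    n <- stacked$n
    loss_log <- data.frame(epoch = integer(0), train = numeric(0),
                           val = numeric(0))
    best <- list(val = Inf, theta = theta, epoch = NA_integer_)
    for (epoch in seq_len(tr$epochs)) {
      lr <- tr$lr_init - epoch * tr$lr_decay
      idx_all <- sample.int(n)
      starts <- seq(1, n, by = tr$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- idx_all[s:min(s + tr$batch_size - 1, n)]
        batch <- slice_batch(stacked, idx)
        params <- unflatten_params(theta, template)
        masks <- if (control$dropout > 0) {
          draw_dropout_masks(length(idx), stacked$n_slots,
                             control$encoder_hidden[2],
                             control$dense_hidden, control$dropout)
        } else NULL
        fwd <- nnet_forward(params, batch, control, masks = masks,
                            keep_cache = TRUE)
        loss <- quantile_loss(batch$Y, fwd$Yhat, q)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d; try a smaller learning rate",
                       epoch))
        }
        grads <- nnet_backward(params, fwd, batch$Y, q, control)
        upd <- adam_step(theta, flatten_params(grads), st, lr)
        theta <- upd$theta
        st <- upd$state
        epoch_loss <- epoch_loss + loss * length(idx)
      }
      train_loss <- epoch_loss / n
      val_loss <- NA_real_
      if (!is.null(val_stacked)) {
        params <- unflatten_params(theta, template)
        vfwd <- nnet_forward(params, val_stacked, control)
        val_loss <- quantile_loss(val_stacked$Y, vfwd$Yhat, q)
        if (val_loss < best$val) {
          best <- list(val = val_loss, theta = theta, epoch = epoch)
        }
      }
      loss_log[epoch, ] <- list(epoch, train_loss, val_loss)
      if (verbose > 0 && epoch %% verbose == 0) {
        message(sprintf("epoch %d: train %.5f%s", epoch, train_loss,
                        if (is.na(val_loss)) ""
                        else sprintf(", val %.5f", val_loss)))
      }
    }
    final_theta <- if (!is.null(val_stacked) && is.finite(best$val)) {
      best$theta
    } else theta
    list(params = unflatten_params(final_theta, template),
         loss_log = loss_log,
         best_epoch = if (!is.null(val_stacked)) best$epoch else tr$epochs)
  })

  # fitted values at the retained parameters (inference mode)
  fitted_n <- nnet_forward(fit$params, stacked, control)$Yhat
  dates <- as.Date(vapply(ws$windows, function(w) as.character(w$date),
                          character(1)))
  obj <- structure(
    list(params = fit$params, control = control, training = training,
         scale = ws$scale, cov_scales = ws$cov_scales,
         feature_names = ws$feature_names, grid = ws$grid, K = K,
         lead = lead, seed = seed, loss_log = fit$loss_log,
         best_epoch = fit$best_epoch, n_windows = stacked$n,
         fitted_dates = dates,
         fitted = fitted_n * ws$scale,
         target = stacked$Y * ws$scale,
         label = series$label, call = cl),
    class = "uvnet"
  )
  obj
}

#' Save or load a fitted forecaster
#'
#' Single-file checkpoint holding configuration, weights, normalization
#' scale and the training log, with a format version tag.
#'
#' @param model A fitted [uvnet()].
#' @param path Checkpoint file path.
#' @return `uvnet_save` returns the path invisibly; `uvnet_load` the
#'   restored model.
#' @export
uvnet_save <- function(model, path) {
  stopifnot(inherits(model, "uvnet"))
  payload <- unclass(model)
  payload$call <- NULL
  saveRDS(list(format = "uvcast-checkpoint-1", model = payload), path)
  invisible(path)
}

#' @rdname uvnet_save
#' @export
uvnet_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "uvcast-checkpoint-1")) {
    stop("not a recognised uvcast checkpoint")
  }
  structure(x$model, class = "uvnet")
}
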