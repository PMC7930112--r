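#' @export
print.uvnet <- function(x, ...) {
  cat("Sequence-to-sequence UV irradiance forecaster\n")
  cat(sprintf("  encoder: BiLSTM(%d) -> LSTM(%d); decoder: LSTM(%d) -> dense(%d) -> dense(1)\n",
              x$control$encoder_hidden[1], x$control$encoder_hidden[2],
              x$control$encoder_hidden[2], x$control$dense_hidden))
  cat(sprintf("  K = %d past days, lead = %d, quantile q = %g, dropout = %g\n",
              x$K, x$lead, x$control$quantile, x$control$dropout))
  cat(sprintf("  trained on %d windows for %d epochs (seed %d); scale = %g mW/m2\n",
              x$n_windows, nrow(x$loss_log), x$seed, x$scale))
  final <- x$loss_log[nrow(x$loss_log), ]
  cat(sprintf("  final training loss %.5f%s\n", final$train,
              if (is.na(final$val)) ""
              else sprintf(", best validation loss %.5f (epoch %d)",
                           min(x$loss_log$val, na.rm = TRUE), x$best_epoch)))
  invisible(x)
}

#' Summarise a fitted forecaster
#'
#' @param object A fitted [uvnet()].
#' @param ... Unused.
#' @return A list of class `summary.uvnet` with parameter counts, the
#'   loss trajectory and training-set residual quartiles.
#' @export
summary.uvnet <- function(object, ...) {
  n_par <- length(flatten_params(object$params))
  res <- object$target - object$fitted
  out <- list(control = object$control, training = object$training,
              K = object$K, lead = object$lead, n_windows = object$n_windows,
              n_parameters = n_par, scale = object$scale,
              loss_first = object$loss_log$train[1],
              loss_final = object$loss_log$train[nrow(object$loss_log)],
              best_epoch = object$best_epoch,
              residual_quartiles = stats::quantile(res, c(0.25, 0.5, 0.75)))
  class(out) <- "summary.uvnet"
  out
}

#' @export
print.summary.uvnet <- function(x, ...) {
  cat(sprintf("uvnet: %d parameters, %d training windows (K = %d, lead = %d)\n",
              x$n_parameters, x$n_windows, x$K, x$lead))
  cat(sprintf("  training loss: %.5f (epoch 1) -> %.5f (final)\n",
              x$loss_first, x$loss_final))
  cat(sprintf("  normalization scale: %g mW/m2\n", x$scale))
  cat("  training residuals (mW/m2, observed - fitted):\n")
  print(round(x$residual_quartiles, 2))
  invisible(x)
}

#' Model coefficients
#'
#' Returns every network weight as one named numeric vector (names encode
#' layer and role, e.g. `enc1f.W42`).
#'
#' @param object A fitted [uvnet()].
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.uvnet <- function(object, ...) flatten_params(object$params)

#' Training-set fitted profiles
#'
#' @param object A fitted [uvnet()].
#' @param ... Unused.
#' @return Matrix of fitted next-day profiles (mW/m2), one row per
#'   training window.
#' @export
fitted.uvnet <- function(object, ...) {
  out <- object$fitted
  dimnames(out) <- list(as.character(object$fitted_dates),
                        slot_labels(object$grid))
  out
}

#' Training-set residuals
#'
#' @param object A fitted [uvnet()].
#' @param ... Unused.
#' @return Matrix `observed - fitted` (mW/m2) over the training windows.
#' @export
residuals.uvnet <- function(object, ...) {
  out <- object$target - object$fitted
  dimnames(out) <- list(as.character(object$fitted_dates),
                        slot_labels(object$grid))
  out
}

#' Training-curve plot
#'
#' Plots the per-epoch training (and, when present, validation) quantile
#' loss.
#'
#' @param x A fitted [uvnet()].
#' @param log_y Use a logarithmic loss axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.uvnet <- function(x, log_y = TRUE, ...) {
  ll <- x$loss_log
  has_val <- any(is.finite(ll$val))
  ylim <- range(c(ll$train, if (has_val) ll$val[is.finite(ll$val)]))
  graphics::plot(ll$epoch, ll$train, type = "l", log = if (log_y) "y" else "",
                 xlab = "epoch", ylab = "quantile loss", ylim = ylim, ...)
  if (has_val) {
    graphics::lines(ll$epoch, ll$val, lty = 2)
    graphics::legend("topright", legend = c("training", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
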