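#' Plot the magnitude responses of a filter bank
#'
#' @param object A [filter_bank()].
#' @param n_freqs Number of frequency grid points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_bank <- function(object, n_freqs = 512, ...) {
  df <- filter_bank_response(
    object, freqs = seq(0.01, object$fs / 2 - 0.01, length.out = n_freqs)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "|H(f)|", colour = "Band",
      title = sprintf("%d-band Butterworth filter bank (order %d, fs = %g Hz)",
                      object$n_bands, object$order, object$fs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot training and test accuracy per epoch
#'
#' @param object A `cnn_fit` from [train_cnn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("train_acc", "test_acc"),
                            names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best$epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "Accuracy (%)", colour = NULL,
                  title = sprintf("Best test accuracy %.1f%% at epoch %d",
                                  object$best$test_acc, object$best$epoch)) +
    ggplot2::theme_minimal()
}

#' Plot per-minute accuracy across the subband sweep
#'
#' @param object An `apnea_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apnea_sweep <- function(object, ...) {
  df <- object[!object$failed, , drop = FALSE]
  df$row <- sprintf("%s %s%s", df$bank_id, df$label,
                    ifelse(df$normalized, "", " (raw)"))
  df$row <- factor(df$row, levels = rev(unique(df$row)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$acc, y = .data$row,
                                   fill = .data$bank_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Per-minute accuracy (%)", y = NULL, fill = "Bank") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
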