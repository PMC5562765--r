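## broom-style accessors and ggplot2 autoplot methods for the result objects.

#' Tidy a pulse spectrum into a long tibble
#'
#' @param x A `pulse_spectrum`.
#' @param ... Unused.
#' @return A tibble with `frequency` (Hz), `band` (`"mean"` or the STFT window
#'   index) and `amplitude` (m/s).
#' @method tidy pulse_spectrum
#' @export
tidy.pulse_spectrum <- function(x, ...) {
  nb <- ncol(x$bands)
  out <- tibble(
    frequency = rep(x$freq, nb + 1),
    band = rep(c(sprintf("band_%02d", seq_len(nb)), "mean"),
               each = length(x$freq)),
    amplitude = c(as.vector(x$bands), x$mean_spectrum)
  )
  out
}

#' One-row summary of a pulse spectrum
#'
#' @param x A `pulse_spectrum` after [extract_fundamental()].
#' @param ... Unused.
#' @return A tibble with `f0`, `heart_rate_bpm`, `A_fund`, `A_harm1`,
#'   `A_harm2`, `window_count` and `no_pulsation`.
#' @method glance pulse_spectrum
#' @export
glance.pulse_spectrum <- function(x, ...) {
  tibble(f0 = x$f0,
         heart_rate_bpm = if (is.na(x$f0)) NA_real_ else heart_rate_bpm(x$f0),
         A_fund = x$A_fund, A_harm1 = x$A_harm1, A_harm2 = x$A_harm2,
         window_count = x$window_count,
         no_pulsation = x$no_pulsation)
}

#' Tidy a velocity field into per-frame statistics
#'
#' @param x A `velocity_field`.
#' @param ... Unused.
#' @return The per-frame stats tibble joined with the frame-mean velocity.
#' @method tidy velocity_field
#' @export
tidy.velocity_field <- function(x, ...) {
  s <- frame_mean_velocity(x)
  out <- x$frame_stats
  out$v_mean <- s$v
  out
}

#' @rdname autoplot-octpulse
#' @param object A result object.
#' @param ... Unused.
#' @name autoplot-octpulse
#' @title Quick plots of octpulse result objects
NULL

#' @rdname autoplot-octpulse
#' @method autoplot pulse_spectrum
#' @export
autoplot.pulse_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot(df[df$band == "mean", ], aes(x = .data$frequency,
                                      y = .data$amplitude * 1e6)) +
    geom_line(data = df[df$band != "mean", ],
              aes(group = .data$band), colour = "grey80") +
    geom_line(colour = "black") +
    labs(x = "frequency (Hz)", y = expression(amplitude ~ (mu * m / s))) +
    theme_minimal()
}

#' @rdname autoplot-octpulse
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, ...) {
  m <- enface_map(object$v_rcs * 1e6, units = "um/s",
                  valid = object$valid | object$interpolated)
  autoplot(m)
}
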