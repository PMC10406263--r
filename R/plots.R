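#' Plot methods for simulation and analysis objects
#'
#' `autoplot()` methods draw the standard views: bolus and signal time
#' courses, relaxation curves, CBV sweeps (peak relaxation change versus
#' simulated blood volume), and the MTT-versus-bolus-duration table.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name dscsim-plots
NULL

#' @rdname dscsim-plots
#' @export
autoplot.agent_bolus <- function(object, ...) {
  ylab <- if (identical(attr(object, "agent"), "Gd")) {
    "[Gd] (mM)"
  } else {
    expression(Delta * Y ~ "(fraction)")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname dscsim-plots
#' @export
autoplot.signal_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "S(t) (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname dscsim-plots
#' @export
autoplot.relaxation_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$dr2s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = expression(Delta * R[2]^"*" ~ (s^-1))) +
    ggplot2::theme_minimal()
}

#' @rdname dscsim-plots
#' @export
autoplot.cbv_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cbv, y = .data$dr2s_max)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "argmax_cbv"),
                        linetype = "dashed") +
    ggplot2::labs(x = "simulated CBV (%)",
                  y = expression(Delta * R["2,max"]^"*" ~ (s^-1)),
                  title = paste0(attr(object, "voxel_kind"), " voxel, ",
                                 attr(object, "paradigm"))) +
    ggplot2::theme_minimal()
}

#' @rdname dscsim-plots
#' @export
autoplot.mtt_duration <- function(object, ...) {
  df <- dplyr::mutate(object, condition = ifelse(
    .data$agent == "Gd", "Gd",
    paste0("dOHb ", .data$bolus_duration, " s")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mtt,
                                   fill = factor(.data$threshold))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = df$mtt_true[1], linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "calculated MTT (s)",
                  fill = "SVD threshold") +
    ggplot2::theme_minimal()
}

#' @rdname dscsim-plots
#' @export
autoplot.paradigm_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$paradigm, y = .data$rcbv,
                               fill = .data$normalization)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rCBV (mL/100g)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
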