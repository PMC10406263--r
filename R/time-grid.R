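#' Fine simulation time grid
#'
#' All tracer kinetics are computed on a fine, regular grid (default step
#' 0.1 s) and only later sampled at the acquisition TR, so that sub-TR
#' delays (1-2 s) and the 2.5 s gamma-variate time-to-peak stay
#' representable.
#'
#' @param duration Total duration (seconds, > 0).
#' @param dt Step (seconds, > 0).
#' @param t0 Time origin (seconds).
#' @return Strictly increasing numeric vector `t0, t0+dt, ..., t0+duration`
#'   (`floor(duration/dt) + 1` samples).
#' @examples
#' length(time_grid(10, dt = 0.1)) # 101
#' @export
time_grid <- function(duration, dt = 0.1, t0 = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  t0 + seq(0, by = dt, length.out = floor(duration / dt) + 1)
}

grid_dt <- function(time) {
  if (length(time) < 2) stop("time grid needs >= 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) {
    stop("time grid must be regular", call. = FALSE)
  }
  dt[1]
}
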