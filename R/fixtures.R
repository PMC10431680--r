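#' Idealised reference activity traces
#'
#' Noise-free synthetic activity traces on the standard simulation grid
#' (default -10 to 200 h, 0.01 h sampling) with analytically known phase
#' statistics, used to unit-test the behaviour measures:
#'
#' * `constant`: activity `value` from stress onset onwards.
#' * `square_pulse`: `baseline` everywhere, `height` on `[t_on, t_off]`.
#' * `raised_cosine`: `amplitude/2 * (1 - cos(2*pi*t/period))` for `t >= 0`
#'   (minimum 0, maximum `amplitude`; with an integer number of periods in
#'   the asymptotic window the asymptotic mean is exactly `amplitude/2`,
#'   so the stochastic-pulsing measure is 2).
#' * `spike_train`: `baseline` plus `n_spikes` rectangular spikes of
#'   `height` and `width` hours, the first starting at `t_first`, spaced
#'   `spacing` hours apart.
#'
#' Pre-stress samples (t < 0) are held at 0 for `raised_cosine` and at
#' `baseline` otherwise.
#'
#' @param kind one of `"constant"`, `"square_pulse"`, `"raised_cosine"`,
#'   `"spike_train"`.
#' @param value constant activity level.
#' @param height,baseline,t_on,t_off square pulse geometry (hours).
#' @param amplitude,period raised cosine peak value and period (hours).
#' @param n_spikes,width,t_first,spacing spike train geometry (hours).
#' @param t_start,t_end,by time grid (hours).
#' @return An `sb_trajectory`-compatible matrix with columns `time_h` and
#'   `sigB` (engine tag `"fixture"`).
#' @examples
#' tr <- reference_trace("raised_cosine", amplitude = 4, period = 1.5)
#' unlist(phase_statistics(tr))
#' @export
reference_trace <- function(kind = c("constant", "square_pulse",
                                     "raised_cosine", "spike_train"),
                            value = 1, height = 10, baseline = 1,
                            t_on = 1, t_off = 2,
                            amplitude = 2, period = 1,
                            n_spikes = 5, width = 0.5, t_first = 10,
                            spacing = 20,
                            t_start = -10, t_end = 200, by = 0.01) {
  kind <- match.arg(kind)
  t <- seq(t_start, t_end, by = by)
  a <- switch(kind,
    constant = rep(value, length(t)),
    square_pulse = ifelse(t >= t_on & t <= t_off, height, baseline),
    raised_cosine = ifelse(t < 0, 0,
                           amplitude / 2 * (1 - cos(2 * pi * t / period))),
    spike_train = {
      x <- rep(baseline, length(t))
      for (i in seq_len(n_spikes)) {
        on <- t_first + (i - 1) * spacing
        x[t >= on & t <= on + width] <- height
      }
      x
    })
  out <- cbind(time_h = t, sigB = a)
  structure(out, class = c("sb_trajectory", class(out)),
            engine = "fixture", seed = NULL, model = "fixture",
            params = NULL, protocol = stress_protocol(t_start, 0, t_end),
            settings = NULL, diagnostics = NULL)
}
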