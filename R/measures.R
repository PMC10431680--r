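#' Phase statistics of a stress-response trajectory
#'
#' Splits the post-stress part of a trajectory into a transient phase
#' (default 0-5 h after stress) and an asymptotic phase (default 5-200 h) and
#' returns the maximum activity in the transient phase, and the maximum and
#' mean activity in the asymptotic phase. Activity is free sigma-B by default
#' or total sigma-B (`[sigB] + [W2sigB]`). Pre-stress samples are always
#' excluded.
#'
#' @param trajectory an `sb_trajectory` (or any matrix with a `time_h` column
#'   and the activity columns).
#' @param activity `"free"` or `"total"`.
#' @param transient,asymptotic phase windows in hours relative to stress
#'   onset.
#' @return A list with `transient_max`, `asymptotic_max`, `asymptotic_mean`.
#' @examples
#' tr <- reference_trace("square_pulse", height = 10, baseline = 1,
#'                       t_on = 1, t_off = 2)
#' phase_statistics(tr)  # (10, 1, 1)
#' @export
phase_statistics <- function(trajectory, activity = c("free", "total"),
                             transient = c(0, 5), asymptotic = c(5, 200)) {
  activity <- match.arg(activity)
  t <- trajectory[, "time_h"]
  a <- activity_trace(trajectory, activity)
  t_end <- max(t)
  if (t_end < asymptotic[2]) {
    warning("trajectory ends at ", t_end, " h; asymptotic phase truncated")
    asymptotic[2] <- t_end
  }
  tr_idx <- t >= transient[1] & t <= transient[2]
  as_idx <- t >= asymptotic[1] & t <= asymptotic[2]
  if (!any(tr_idx) || !any(as_idx))
    stop("trajectory does not cover the post-stress measurement windows")
  list(transient_max = max(a[tr_idx]),
       asymptotic_max = max(a[as_idx]),
       asymptotic_mean = mean(a[as_idx]))
}

activity_trace <- function(trajectory, activity = "free") {
  a <- trajectory[, "sigB"]
  if (activity == "total" && "W2sigB" %in% colnames(trajectory))
    a <- a + trajectory[, "W2sigB"]
  a
}

#' Behaviour magnitudes of an ensemble
#'
#' For each ensemble member computes the single-response-pulse magnitude
#' `M_srp` (transient maximum divided by asymptotic maximum) and the
#' stochastic-pulsing magnitude `M_sp` (asymptotic maximum divided by
#' asymptotic mean), then averages the per-member ratios over the ensemble.
#' Dividing the transient pulse by the asymptotic maximum penalises `M_srp`
#' whenever asymptotic pulses occur, so the two measures cannot both be large
#' for the same parameter set. A constant-activity trajectory scores 1 on
#' both. If a denominator falls below `guard` the measure is defined as 1
#' (no behaviour).
#'
#' @param ensemble an `sb_ensemble`, or a list of trajectories.
#' @inheritParams phase_statistics
#' @param guard denominator guard (default 1e-12).
#' @return An object of class `sb_scores`: list with per-member vectors
#'   `M_srp`, `M_sp`, their ensemble means `mean_M_srp`, `mean_M_sp`, and the
#'   per-member phase statistics.
#' @examples
#' tr <- reference_trace("raised_cosine", amplitude = 2, period = 1)
#' behaviour_magnitudes(list(tr))$mean_M_sp  # 2
#' @export
behaviour_magnitudes <- function(ensemble, activity = c("free", "total"),
                                 transient = c(0, 5), asymptotic = c(5, 200),
                                 guard = 1e-12) {
  activity <- match.arg(activity)
  if (inherits(ensemble, "sb_trajectory")) ensemble <- list(ensemble)
  if (length(ensemble) == 0) stop("empty ensemble")
  ph <- lapply(ensemble, phase_statistics, activity = activity,
               transient = transient, asymptotic = asymptotic)
  M_srp <- vapply(ph, function(s)
    if (s$asymptotic_max < guard) 1 else s$transient_max / s$asymptotic_max,
    numeric(1))
  M_sp <- vapply(ph, function(s)
    if (s$asymptotic_mean < guard) 1 else s$asymptotic_max / s$asymptotic_mean,
    numeric(1))
  structure(list(M_srp = M_srp, M_sp = M_sp,
                 mean_M_srp = mean(M_srp), mean_M_sp = mean(M_sp),
                 phase = ph, n = length(ensemble), activity = activity),
            class = "sb_scores")
}

#' @export
print.sb_scores <- function(x, ...) {
  cat("sb_scores over", x$n, "member(s):\n")
  cat(sprintf("  M_srp: mean %.4g (range %.4g..%.4g)\n",
              x$mean_M_srp, min(x$M_srp), max(x$M_srp)))
  cat(sprintf("  M_sp : mean %.4g (range %.4g..%.4g)\n",
              x$mean_M_sp, min(x$M_sp), max(x$M_sp)))
  invisible(x)
}

#' Excess behaviour magnitudes
#'
#' The degree to which each behaviour surpasses the other:
#' `M*_srp = max(M_srp - M_sp, 0)` and symmetrically for `M*_sp` (the
#' equality case maps to (0, 0)). At most one of the two is positive, so
#' `M*_srp * M*_sp = 0` always.
#'
#' @param M_srp,M_sp numeric vectors of equal length.
#' @return A list with vectors `M_srp_star` and `M_sp_star`.
#' @examples
#' excess_magnitudes(5, 2)  # (3, 0)
#' @export
excess_magnitudes <- function(M_srp, M_sp) {
  stopifnot(length(M_srp) == length(M_sp))
  list(M_srp_star = pmax(M_srp - M_sp, 0),
       M_sp_star = pmax(M_sp - M_srp, 0))
}

#' Behaviour-magnitude profile along a parameter grid
#'
#' Container for ensemble-mean `M_srp(p)` and `M_sp(p)` along a
#' strictly-increasing parameter grid, used by the distinctness and
#' sensitivity measures.
#'
#' @param param swept parameter name.
#' @param grid strictly increasing numeric grid.
#' @param M_srp,M_sp ensemble-mean magnitudes at each grid value.
#' @return An object of class `sb_profile`.
#' @export
measure_profile <- function(param, grid, M_srp, M_sp) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0),
            length(M_srp) == length(grid), length(M_sp) == length(grid))
  structure(list(param = param, grid = grid, M_srp = M_srp, M_sp = M_sp),
            class = "sb_profile")
}

profile_integral <- function(y, grid, integration) {
  if (integration == "trapezoid") {
    sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  } else {
    sum(y) * mean(diff(grid))
  }
}

#' Distinctness of generating both behaviours along one parameter
#'
#' Measures whether sweeping a single parameter can elicit each behaviour
#' distinctly (one at a time). With `I_srp`, `I_sp` the integrals of the
#' excess magnitudes `M*` over the grid and `I_max` the integral of their
#' pointwise maximum, the default ratio form is
#' `D = 2 * I_srp * I_sp / I_max`. The alternative area form uses the areas
#' between/below the raw magnitude curves: `A_srp` (below `M_srp`, above
#' `M_sp`; equal to `I_srp`), `A_sp` symmetrically, and the shared area
#' `A_srp_sp` below both curves, giving
#' `D = A_srp * A_sp / (A_srp + A_srp_sp + A_sp)`. The two published forms
#' are not algebraically identical; both are returned, `method` picks which
#' one populates `$D`. Neither form is guaranteed to stay below 1 for
#' unbounded magnitudes; the value is reported as computed.
#'
#' @param profile an [measure_profile()] object.
#' @param method `"ratio"` (default) or `"area"`.
#' @param integration `"trapezoid"` (default) or `"sum"` (plain grid sums).
#' @return A list with `D`, `D_ratio`, `D_area`, the areas `A_srp`, `A_sp`,
#'   `A_srp_sp`, and `degenerate` (`TRUE` when every excess magnitude is 0).
#' @export
dual_distinctness <- function(profile, method = c("ratio", "area"),
                              integration = c("trapezoid", "sum")) {
  method <- match.arg(method)
  integration <- match.arg(integration)
  stopifnot(inherits(profile, "sb_profile"))
  ex <- excess_magnitudes(profile$M_srp, profile$M_sp)
  I_srp <- profile_integral(ex$M_srp_star, profile$grid, integration)
  I_sp <- profile_integral(ex$M_sp_star, profile$grid, integration)
  I_max <- profile_integral(pmax(ex$M_srp_star, ex$M_sp_star), profile$grid,
                            integration)
  A_shared <- profile_integral(pmin(profile$M_srp, profile$M_sp),
                               profile$grid, integration)
  degenerate <- I_max <= 0
  D_ratio <- if (degenerate) 0 else 2 * I_srp * I_sp / I_max
  denom <- I_srp + I_sp + A_shared
  D_area <- if (denom <= 0) 0 else I_srp * I_sp / denom
  list(D = if (method == "ratio") D_ratio else D_area,
       D_ratio = D_ratio, D_area = D_area,
       A_srp = I_srp, A_sp = I_sp, A_srp_sp = A_shared,
       degenerate = degenerate)
}

#' Distinctness of generating one behaviour
#'
#' Squared-area-over-total variants favouring parameter regions where one
#' behaviour is prominent in absolute terms: ratio form
#' `D_srp = I_srp^2 / I_max` (and symmetrically `D_sp`), area form
#' `D_srp = A_srp^2 / (A_srp + A_sp + A_srp_sp)`.
#'
#' @inheritParams dual_distinctness
#' @return A list with `D_srp`, `D_sp`, both forms of each, the areas, and
#'   `degenerate`.
#' @export
single_distinctness <- function(profile, method = c("ratio", "area"),
                                integration = c("trapezoid", "sum")) {
  method <- match.arg(method)
  integration <- match.arg(integration)
  dd <- dual_distinctness(profile, integration = integration)
  I_max <- dd$A_srp + dd$A_sp  # excess magnitudes are mutually exclusive
  denom_area <- dd$A_srp + dd$A_sp + dd$A_srp_sp
  ratio <- function(I) if (I_max <= 0) 0 else I^2 / I_max
  area <- function(I) if (denom_area <= 0) 0 else I^2 / denom_area
  out <- list(D_srp_ratio = ratio(dd$A_srp), D_sp_ratio = ratio(dd$A_sp),
              D_srp_area = area(dd$A_srp), D_sp_area = area(dd$A_sp),
              A_srp = dd$A_srp, A_sp = dd$A_sp, A_srp_sp = dd$A_srp_sp,
              degenerate = I_max <= 0)
  if (method == "ratio") {
    out$D_srp <- out$D_srp_ratio; out$D_sp <- out$D_sp_ratio
  } else {
    out$D_srp <- out$D_srp_area; out$D_sp <- out$D_sp_area
  }
  out
}

#' Sensitivity of a behaviour magnitude to a parameter
#'
#' Squared-successive-difference sensitivity along a grid of n values:
#' `C = (n - 1) * sum_i (M(p[i+1]) - M(p[i]))^2`. The `(n - 1)` factor
#' removes the bias from the grid density (a linear rise by `c` over the full
#' grid scores `c^2` for any n); squaring emphasises sudden changes over
#' gradual ones. Optionally normalised by a reference maximum for display.
#'
#' @param M magnitudes along the grid (length n >= 2).
#' @param normalise optional positive scalar to divide the result by.
#' @return The sensitivity (numeric scalar).
#' @examples
#' magnitude_sensitivity(c(0, 1))  # 1
#' magnitude_sensitivity(seq(0, 3, length.out = 7))  # 9
#' @export
magnitude_sensitivity <- function(M, normalise = NULL) {
  n <- length(M)
  stopifnot(n >= 2)
  C <- (n - 1) * sum(diff(M)^2)
  if (!is.null(normalise)) {
    stopifnot(normalise > 0)
    C <- C / normalise
  }
  C
}

#' Classifier thresholds
#'
#' Heuristic thresholds used by [classify_response()]. These operationalise
#' qualitative response categories and are tunable configuration, not model
#' constants.
#'
#' @param sp_min minimum ensemble-mean `M_sp` to call stochastic pulsing.
#' @param srp_min minimum ensemble-mean `M_srp` to call a single pulse.
#' @param osc_min minimum spectral concentration (fraction of asymptotic
#'   spectral power in the dominant frequency bin) to call an oscillation.
#' @param osc_sp_band `M_sp` range compatible with a clean oscillation
#'   (a sinusoid scores 2).
#' @param response_fold activity must exceed this multiple of the pre-stress
#'   baseline (plus `floor`) to count as a response at all.
#' @param elevated_fold asymptotic mean above this multiple of baseline
#'   (plus `floor`) counts as persistently elevated activity.
#' @param floor absolute activity floor guarding the fold comparisons, in
#'   concentration units.
#' @param f_min_periods dominant-frequency search ignores periods longer
#'   than the asymptotic window divided by this count (suppresses red-noise
#'   drift).
#' @return A list of thresholds.
#' @export
classifier_thresholds <- function(sp_min = 4, srp_min = 2, osc_min = 0.2,
                                  osc_sp_band = c(1.4, 4),
                                  response_fold = 3, elevated_fold = 10,
                                  floor = 0.01, f_min_periods = 8) {
  as.list(environment())
}

#' Classify the ensemble response
#'
#' Deterministic heuristic classifier mapping an ensemble to one of
#' `no_response`, `single_pulse`, `stochastic_pulsing`, `oscillation`,
#' `sustained_activity`, using the behaviour magnitudes, the asymptotic mean
#' relative to the pre-stress baseline, and the concentration of asymptotic
#' spectral power in a dominant frequency (sustained limit cycles concentrate
#' power in one bin; irregular pulsing spreads it). Decision order: absence
#' of any response; stochastic pulsing (`M_sp` large); oscillation (moderate
#' `M_sp` with a sharp spectral peak and elevated mean); persistently
#' elevated activity; single response pulse; otherwise no response (flagged
#' ambiguous).
#'
#' @param ensemble an `sb_ensemble` (or list of trajectories).
#' @inheritParams phase_statistics
#' @param thresholds a [classifier_thresholds()] list.
#' @return An object of class `sb_classification`: list with `label`, the
#'   diagnostic `scores`, and a `note` for ambiguous calls.
#' @export
classify_response <- function(ensemble, activity = c("free", "total"),
                              thresholds = classifier_thresholds()) {
  activity <- match.arg(activity)
  if (inherits(ensemble, "sb_trajectory")) ensemble <- list(ensemble)
  th <- thresholds
  sc <- behaviour_magnitudes(ensemble, activity = activity)
  t <- ensemble[[1]][, "time_h"]
  pre_idx <- t < 0 & t >= max(min(t), -5)
  baseline <- if (any(pre_idx))
    mean(vapply(ensemble, function(tr) mean(activity_trace(tr, activity)[pre_idx]),
                numeric(1)))
  else 0
  t_max <- mean(vapply(sc$phase, function(s) s$transient_max, numeric(1)))
  a_max <- mean(vapply(sc$phase, function(s) s$asymptotic_max, numeric(1)))
  a_mean <- mean(vapply(sc$phase, function(s) s$asymptotic_mean, numeric(1)))
  osc <- mean(vapply(ensemble, function(tr)
    spectral_concentration(tr, activity, th$f_min_periods), numeric(1)))
  ref <- th$response_fold * baseline + th$floor
  elevated <- a_mean > th$elevated_fold * baseline + th$floor
  scores <- list(mean_M_srp = sc$mean_M_srp, mean_M_sp = sc$mean_M_sp,
                 baseline = baseline, transient_max = t_max,
                 asymptotic_max = a_max, asymptotic_mean = a_mean,
                 spectral_concentration = osc)
  note <- NULL
  label <- if (t_max <= ref && a_max <= ref) {
    "no_response"
  } else if (sc$mean_M_sp >= th$sp_min) {
    "stochastic_pulsing"
  } else if (osc >= th$osc_min && sc$mean_M_sp >= th$osc_sp_band[1] &&
             sc$mean_M_sp <= th$osc_sp_band[2] && elevated) {
    "oscillation"
  } else if (elevated && sc$mean_M_sp < th$osc_sp_band[1]) {
    "sustained_activity"
  } else if (sc$mean_M_srp >= th$srp_min) {
    "single_pulse"
  } else {
    note <- "ambiguous: no category matched cleanly; defaulting to no_response"
    "no_response"
  }
  structure(list(label = label, scores = scores, note = note,
                 thresholds = th),
            class = "sb_classification")
}

# fraction of asymptotic-phase spectral power in the dominant bin, ignoring
# periods longer than window/f_min_periods
spectral_concentration <- function(trajectory, activity = "free",
                                   f_min_periods = 8, asymptotic = c(5, 200)) {
  t <- trajectory[, "time_h"]
  idx <- t >= asymptotic[1] & t <= min(asymptotic[2], max(t))
  a <- activity_trace(trajectory, activity)[idx]
  n <- length(a)
  if (n < 16) return(0)
  a <- a - mean(a)
  if (sqrt(mean(a^2)) < 1e-12) return(0)
  pw <- Mod(stats::fft(a)[2:floor(n / 2)])^2
  k_min <- max(1L, as.integer(ceiling(f_min_periods)))  # cycles per window
  pw_band <- pw[k_min:length(pw)]
  tot <- sum(pw)
  if (tot <= 0) return(0)
  max(pw_band) / tot
}

#' @export
print.sb_classification <- function(x, ...) {
  cat("response class:", x$label, "\n")
  s <- x$scores
  cat(sprintf("  mean M_srp %.3g | mean M_sp %.3g | asympt mean %.4g | spectral conc %.3g\n",
              s$mean_M_srp, s$mean_M_sp, s$asymptotic_mean,
              s$spectral_concentration))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
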