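#' Grid parameter sweep with seeded per-cell ensembles
#'
#' Evaluates an ensemble-based scoring function over a full factorial grid of
#' parameter values. Each cell gets a deterministic seed block derived from
#' `base_seed` and the cell index, so any sub-scan can be reproduced in
#' isolation and the result is independent of evaluation order. Cell
#' failures are recorded (scores set to `NA`) and the scan continues.
#'
#' @param axes named list of numeric grids, e.g.
#'   `list(eta = c(0.01, 0.05), kK2 = c(7, 9))`.
#' @param evaluator either `NULL` (default scoring: CLE ensemble of the core
#'   model scored with [behaviour_magnitudes()]) or a function
#'   `function(params, n, base_seed)` returning a list with at least
#'   `mean_M_srp` and `mean_M_sp`.
#' @param params base [sb_params()]; each cell overrides the axis parameters
#'   (the name `p_prod` is mapped through the substitution with `p_frac`
#'   held fixed, and vice versa).
#' @param n ensemble size per cell.
#' @param base_seed root seed.
#' @param production_form forwarded to [core_network()].
#' @param settings [sim_settings()] used by the default evaluator.
#' @param seed_stride per-cell seed spacing (>= n).
#' @return An `sb_scan`: data frame with one row per cell (axis values,
#'   `M_srp`, `M_sp`, `seed`, `ok`), with the axes stored as an attribute.
#' @examples
#' \donttest{
#' sc <- sweep_scan(list(p_stress = c(0.2, 0.4)), n = 4, base_seed = 1,
#'                  settings = sim_settings(dt = 0.002))
#' }
#' @export
sweep_scan <- function(axes, evaluator = NULL, params = sb_params(), n = 20,
                       base_seed = 1L, production_form = "ratio",
                       settings = sim_settings(), seed_stride = NULL) {
  stopifnot(is.list(axes), length(axes) >= 1, !is.null(names(axes)),
            all(nzchar(names(axes))))
  if (is.null(seed_stride)) seed_stride <- max(n, 1000L)
  if (is.null(evaluator))
    evaluator <- function(p, n, seed) {
      net <- core_network(p, production_form = production_form)
      behaviour_magnitudes(simulate_ensemble(net, p, settings = settings,
                                             n = n, base_seed = seed))
    }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- as.integer(base_seed + (i - 1L) * seed_stride)
    p <- params
    for (ax in names(axes)) p <- set_swept_param(p, ax, grid[i, ax])
    sc <- tryCatch(evaluator(p, n, cell_seed), error = function(e) NULL)
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       data.frame(M_srp = if (is.null(sc)) NA_real_ else sc$mean_M_srp,
                                  M_sp = if (is.null(sc)) NA_real_ else sc$mean_M_sp,
                                  seed = cell_seed, ok = !is.null(sc)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sb_scan", class(out)),
            axes = axes, n = n, base_seed = base_seed)
}

#' Reduce a scan by maximising a score over one axis
#'
#' For every combination of the remaining axes, takes the maximum of `score`
#' over the named axis and records the axis value achieving it (the argmax).
#' This is the reduction behind heatmaps that show, per cell, the best
#' response achievable by tuning the stress level.
#'
#' @param scan an `sb_scan`.
#' @param parameter name of the reduced axis.
#' @param score `"M_srp"` or `"M_sp"`.
#' @return A data frame with the remaining axes, `score`, and
#'   `argmax_<parameter>`.
#' @export
max_over_parameter <- function(scan, parameter, score = c("M_sp", "M_srp")) {
  score <- match.arg(score)
  axes <- attr(scan, "axes")
  stopifnot(parameter %in% names(axes))
  others <- setdiff(names(axes), parameter)
  df <- as.data.frame(scan)
  if (length(others) == 0) {
    i <- which.max(df[[score]])
    out <- data.frame(score = df[[score]][i], argmax = df[[parameter]][i])
    names(out)[2] <- paste0("argmax_", parameter)
    return(out)
  }
  key <- interaction(df[others], drop = TRUE)
  parts <- lapply(split(df, key), function(g) {
    i <- which.max(g[[score]])
    cbind(g[i, others, drop = FALSE],
          stats::setNames(data.frame(g[[score]][i], g[[parameter]][i]),
                          c("score", paste0("argmax_", parameter))))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Behaviour-magnitude profile and distinctness along one parameter
#'
#' Sweeps a single parameter over a grid, evaluating ensemble-mean `M_srp`
#' and `M_sp` at every point, and returns the profile together with the
#' distinctness statistics: the dual measure (both behaviours elicited
#' distinctly somewhere along the sweep) and the per-behaviour measures.
#'
#' @param param swept parameter name (e.g. `"p_prod"`, `"p_stress"`).
#' @param range length-2 numeric range.
#' @param grid_n number of grid points.
#' @param params base [sb_params()].
#' @param n ensemble size per grid point.
#' @param base_seed root seed.
#' @param spacing `"linear"` (default) or `"log"`.
#' @param model `"core"` or `"modified"` (the modified model adds upstream
#'   phosphatase noise).
#' @inheritParams sweep_scan
#' @return A list with `profile` (an [measure_profile()]), `dual`
#'   (from [dual_distinctness()]), `single` (from [single_distinctness()])
#'   and the per-point scan data.
#' @export
distinctness_profile <- function(param, range, grid_n = 8,
                                 params = sb_params(), n = 20,
                                 base_seed = 1L, spacing = c("linear", "log"),
                                 model = c("core", "modified"),
                                 production_form = "ratio",
                                 settings = sim_settings()) {
  spacing <- match.arg(spacing)
  model <- match.arg(model)
  grid <- if (spacing == "log")
    exp(seq(log(range[1]), log(range[2]), length.out = grid_n))
  else seq(range[1], range[2], length.out = grid_n)
  build <- if (model == "core") core_network else modified_network
  evaluator <- function(p, n, seed) {
    net <- build(p, production_form = production_form)
    behaviour_magnitudes(simulate_ensemble(net, p, settings = settings,
                                           n = n, base_seed = seed))
  }
  scan <- sweep_scan(stats::setNames(list(grid), param), evaluator, params,
                     n = n, base_seed = base_seed)
  prof <- measure_profile(param, grid, scan$M_srp, scan$M_sp)
  list(profile = prof, dual = dual_distinctness(prof),
       single = single_distinctness(prof), scan = scan)
}

#' Locate the best-scoring cell of a scan
#'
#' Argmax over the scan cells; ties are broken to the lowest cell index and
#' flagged.
#'
#' @param scan an `sb_scan` (or any data frame with the score column).
#' @param score column name to maximise.
#' @return A list with `index`, `cell` (the row), `score`, and `tie`.
#' @export
locate_optimum <- function(scan, score = "M_sp") {
  v <- scan[[score]]
  if (all(is.na(v))) stop("no successful cells in scan")
  best <- max(v, na.rm = TRUE)
  hits <- which(!is.na(v) & v == best)
  list(index = hits[1], cell = as.data.frame(scan)[hits[1], , drop = FALSE],
       score = best, tie = length(hits) > 1)
}

#' @export
print.sb_scan <- function(x, ...) {
  axes <- attr(x, "axes")
  cat("sb_scan:", paste(sprintf("%s (%d)", names(axes), lengths(axes)),
                        collapse = " x "),
      "=", nrow(x), "cells, n =", attr(x, "n"), "per cell\n")
  cat("  failed cells:", sum(!x$ok), "\n")
  invisible(x)
}
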