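#' Find a deterministic steady state
#'
#' Solves for a root of the post-stress deterministic drift of the core
#' model. Total phosphatase is conserved, which makes the raw drift Jacobian
#' structurally singular, so the solver works in reduced coordinates: the
#' bound phosphatase `PVP` is eliminated through `P + PVP = p_total` (the
#' post-stress total equals `p_stress`). Newton iterations with the analytic
#' Jacobian start from the supplied guess and, if needed, from a long ODE
#' relaxation (an independent `deSolve::lsoda` integration of the same
#' drift).
#'
#' @param params an [sb_params()] object.
#' @param initial_guess optional named state vector used as the first Newton
#'   start.
#' @param network an `sb_network` (core model; default builds one).
#' @param stress_applied if `TRUE` (default) the phosphatase total is
#'   `p_stress`; otherwise the pre-stress total `p_init` is used.
#' @param tol residual max-norm tolerance (default 1e-11).
#' @param max_iter Newton iteration cap.
#' @return A list with `state` (named vector, all 10 species), `residual`
#'   (drift max-norm at the solution), `converged`, and `p_total`.
#' @examples
#' ss <- find_steady_state(sb_params(p_stress = 0.4))
#' ss$state[["P"]] + ss$state[["PVP"]]  # 0.4
#' @export
find_steady_state <- function(params, initial_guess = NULL,
                              network = core_network(params),
                              stress_applied = TRUE,
                              tol = 1e-11, max_iter = 200) {
  validate_params(params)
  if (network$model != "core")
    stop("steady-state analysis is implemented for the core model")
  p_total <- if (stress_applied) params$p_stress else params$p_init
  if (!is.null(initial_guess)) {
    res <- newton_reduced(network, params, as_state(network, initial_guess),
                          p_total, tol, max_iter)
    if (res$converged) return(res)
  }
  # relaxation guess: integrate the drift for a long horizon
  res <- newton_reduced(network, params, relax_state(network, params, p_total),
                        p_total, tol, max_iter)
  res
}

# eliminate PVP = p_total - P; Newton on the remaining 9 coordinates
reduced_index <- function(network) setdiff(seq_along(network$species),
                                           match("PVP", network$species))

expand_state <- function(network, xr, p_total) {
  st <- stats::setNames(numeric(length(network$species)), network$species)
  st[reduced_index(network)] <- xr
  st[["PVP"]] <- p_total - st[["P"]]
  st
}

reduced_drift <- function(network, params, xr, p_total) {
  st <- expand_state(network, xr, p_total)
  drift(network, st, params)[reduced_index(network)]
}

reduced_jacobian <- function(network, params, xr, p_total) {
  st <- expand_state(network, xr, p_total)
  J <- drift_jacobian(network, st, params)
  keep <- reduced_index(network)
  ip <- match("P", network$species)
  ipvp <- match("PVP", network$species)
  # chain rule for PVP = p_total - P
  Jr <- J[keep, keep, drop = FALSE]
  Jr[, network$species[keep] == "P"] <-
    Jr[, network$species[keep] == "P", drop = FALSE] - J[keep, ipvp]
  Jr
}

newton_reduced <- function(network, params, guess, p_total, tol, max_iter) {
  keep <- reduced_index(network)
  xr <- guess[keep]
  xr[names(xr) == "P"] <- min(max(guess[["P"]], 0), p_total)
  for (it in seq_len(max_iter)) {
    G <- reduced_drift(network, params, xr, p_total)
    g0 <- max(abs(G))
    if (g0 < tol) break
    J <- reduced_jacobian(network, params, xr, p_total)
    delta <- tryCatch(solve(J, -G), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    for (h in 1:10) {
      xt <- xr + step * delta
      gt <- max(abs(reduced_drift(network, params, xt, p_total)))
      if (is.finite(gt) && gt < g0) break
      step <- step / 2
    }
    xr <- xt
  }
  st <- expand_state(network, xr, p_total)
  resid <- max(abs(drift(network, st, params)))
  list(state = st, residual = resid, converged = resid < 1e-9,
       p_total = p_total)
}

relax_state <- function(network, params, p_total, t_final = 1000) {
  st <- init_state(network, params)
  st[["P"]] <- p_total
  spec <- compile_spec(network, params)
  res <- cle_simulate_cpp(spec, st, 0, t_final / 2, t_final, 0.002,
                          as.integer(t_final / 0.002),
                          numeric(length(st)), FALSE, 1e-10, 20L)
  stats::setNames(res$x[nrow(res$x), ], network$species)
}

#' Linear stability at a steady state
#'
#' Evaluates the analytic drift Jacobian at a steady state, removes the
#' structurally neutral direction from total-phosphatase conservation by
#' working in the reduced coordinates (PVP eliminated), and classifies the
#' state by the leading eigenvalue real part: `"stable"` if below
#' `-marginal_band`, `"unstable"` if above `+marginal_band`, `"marginal"`
#' in between.
#'
#' @param params an [sb_params()] object.
#' @param steady_state named state vector (a root of the drift).
#' @param network core `sb_network`.
#' @param stress_applied logical, selects the conserved phosphatase total.
#' @param marginal_band half-width of the marginal classification band.
#' @return A list with `leading` (largest real part), `eigenvalues` (of the
#'   reduced Jacobian), `stable` (logical; `NA` when marginal) and `flag`.
#' @export
stability_at <- function(params, steady_state, network = core_network(params),
                         stress_applied = TRUE, marginal_band = 1e-8) {
  p_total <- if (stress_applied) params$p_stress else params$p_init
  xr <- as_state(network, steady_state)[reduced_index(network)]
  J <- reduced_jacobian(network, params, xr, p_total)
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  flag <- if (lead < -marginal_band) "stable"
          else if (lead > marginal_band) "unstable" else "marginal"
  list(leading = lead, eigenvalues = ev,
       stable = if (flag == "marginal") NA else flag == "stable",
       flag = flag)
}

#' Steady-state stability branch along one parameter
#'
#' Sweeps one parameter over a grid (log-spaced by default, tenfold down and
#' up of the current value unless an explicit range is given), solving for
#' the post-stress steady state at each value with warm starts from the
#' previous branch point, and classifying stability from the reduced drift
#' Jacobian eigenvalues. Instability intervals are reported as sub-ranges of
#' the swept parameter. `p_prod` may be swept directly; it is mapped through
#' the substitution `p_stress = sqrt(p_prod * p_frac)`,
#' `kP = sqrt(p_prod / p_frac)` with `p_frac` held at its current value.
#'
#' @param param name of the swept parameter (any rate parameter, `p_stress`,
#'   or `p_prod`).
#' @param range length-2 numeric range; defaults to tenfold down/up of the
#'   parameter's current value.
#' @param params base [sb_params()].
#' @param n_points grid size.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return An object of class `sb_branch`: data frame with the parameter
#'   value, steady free sigma-B, leading eigenvalue real part, stability
#'   flag and residual; plus attributes `unstable_intervals` and `param`.
#' @examples
#' br <- branch_scan("p_stress", c(0.1, 10), sb_params(), n_points = 11)
#' any(br$flag == "unstable")
#' @export
branch_scan <- function(param, range = NULL, params = sb_params(),
                        n_points = 41, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  validate_params(params)
  base_value <- if (param == "p_prod") unname(param_substitution(params)["p_prod"])
                else params[[param]]
  if (is.null(base_value)) stop("unknown parameter: ", param)
  if (is.null(range)) range <- c(base_value / 10, base_value * 10)
  grid <- if (spacing == "log")
    exp(seq(log(range[1]), log(range[2]), length.out = n_points))
  else seq(range[1], range[2], length.out = n_points)
  rows <- vector("list", n_points)
  prev_state <- NULL
  for (i in seq_len(n_points)) {
    pi_ <- set_swept_param(params, param, grid[i])
    net <- core_network(pi_)
    ss <- tryCatch(find_steady_state(pi_, initial_guess = prev_state,
                                     network = net),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) {
      rows[[i]] <- data.frame(value = grid[i], sigB = NA_real_,
                              leading = NA_real_, flag = "missing",
                              residual = if (is.null(ss)) NA_real_ else ss$residual)
      next
    }
    prev_state <- ss$state
    stb <- stability_at(pi_, ss$state, network = net)
    rows[[i]] <- data.frame(value = grid[i], sigB = ss$state[["sigB"]],
                            leading = stb$leading, flag = stb$flag,
                            residual = ss$residual)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  unstable <- out$flag == "unstable" & !is.na(out$flag)
  intervals <- list()
  if (any(unstable)) {
    r <- rle(unstable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values))
      intervals[[length(intervals) + 1]] <- c(out$value[starts[k]], out$value[ends[k]])
  }
  structure(out, class = c("sb_branch", class(out)),
            param = param, unstable_intervals = intervals)
}

set_swept_param <- function(params, param, value) {
  if (param == "p_prod") {
    pf <- unname(param_substitution(params)["p_frac"])
    sub <- substitution_to_rates(value, pf)
    params$p_stress <- sub[["p_stress"]]
    params$kP <- sub[["kP"]]
  } else if (param == "p_frac") {
    pp <- unname(param_substitution(params)["p_prod"])
    sub <- substitution_to_rates(pp, value)
    params$p_stress <- sub[["p_stress"]]
    params$kP <- sub[["kP"]]
  } else if (param %in% names(params)) {
    params[[param]] <- value
  } else {
    stop("unknown parameter: ", param)
  }
  validate_params(params)
  params
}

#' @export
print.sb_branch <- function(x, ...) {
  cat("sb_branch over", attr(x, "param"), ":", nrow(x), "points\n")
  iv <- attr(x, "unstable_intervals")
  if (length(iv)) {
    cat("  unstable sub-interval(s):\n")
    for (r in iv) cat(sprintf("    [%.4g, %.4g]\n", r[1], r[2]))
  } else cat("  no unstable points\n")
  invisible(x)
}

#' @export
plot.sb_branch <- function(x, ...) {
  col <- ifelse(x$flag == "unstable", 2, ifelse(x$flag == "marginal", 3, 1))
  graphics::plot(x$value, x$sigB, log = "x", col = col, pch = 16,
                 xlab = attr(x, "param"), ylab = "steady [sigB]", ...)
  invisible(x)
}
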