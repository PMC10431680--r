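#' Simulation settings
#'
#' Numerical settings shared by the engines. The chemical-Langevin and ODE
#' engines use a fixed-step drift-implicit, diffusion-explicit Euler-Maruyama
#' scheme: step `dt` (hours), damped Newton on the implicit drift equation
#' with analytic Jacobian (`newton_tol` on the max-norm residual,
#' `newton_max` iterations, step-halving fallback). One independent Wiener
#' increment per reaction per step is drawn in fixed reaction order, so a
#' given seed reproduces the path exactly. `output_dt` is the sampling
#' interval of the stored trajectory and must be an integer multiple of `dt`.
#'
#' @param dt integrator step in hours (default 0.001).
#' @param output_dt trajectory sampling interval in hours (default 0.01).
#' @param newton_tol,newton_max Newton tolerance and iteration cap.
#' @param init_mode `"zero"` (all species 0 except phosphatase at `p_init`,
#'   relaxed through the burn-in) or `"steady"` (start at the deterministic
#'   pre-stress steady state).
#' @return An object of class `sb_settings`.
#' @export
sim_settings <- function(dt = 0.001, output_dt = 0.01,
                         newton_tol = 1e-10, newton_max = 20L,
                         init_mode = c("zero", "steady")) {
  stopifnot(dt > 0, output_dt > 0)
  r <- output_dt / dt
  if (abs(r - round(r)) > 1e-8)
    stop("output_dt must be an integer multiple of dt")
  structure(list(dt = dt, output_dt = output_dt,
                 newton_tol = newton_tol, newton_max = as.integer(newton_max),
                 init_mode = match.arg(init_mode)),
            class = "sb_settings")
}

# flatten network + params into the numeric arrays the C++ engines consume
compile_spec <- function(network, params) {
  validate_params(params)
  rxn <- network$rxn
  typecode <- c(production = 0L, mass1 = 1L, mass2 = 2L, dimer = 3L)
  idx <- function(nm) ifelse(is.na(nm), -1L, match(nm, network$species) - 1L)
  rate <- vapply(seq_len(nrow(rxn)), function(j) {
    if (is.na(rxn$rate_param[j])) 1 else params[[rxn$rate_param[j]]]
  }, numeric(1))
  list(S = network$S * 1.0,
       type = unname(typecode[rxn$type]),
       i1 = as.integer(idx(rxn$r1)), i2 = as.integer(idx(rxn$r2)),
       rate = rate,
       nscale = ifelse(rxn$noise_group == "upstream", params$eta_amp, params$eta),
       v0 = params$v0, F = params$F, K = params$K,
       form = if (network$production_form == "offset") 0L else 1L,
       isigb = match("sigB", network$species) - 1L)
}

stress_vector <- function(network, params) {
  dp <- params$p_stress - params$p_init
  sa <- stats::setNames(numeric(length(network$species)), network$species)
  sa[["P"]] <- dp
  if (network$model == "modified") sa[["PI"]] <- dp
  sa
}

start_state <- function(network, params, settings) {
  if (settings$init_mode == "steady") {
    pre <- params
    pre$p_stress <- pre$p_init  # degenerate stress: pre-stress dynamics
    ss <- find_steady_state(pre, network = network, stress_applied = FALSE)
    ss$state
  } else {
    init_state(network, params)
  }
}

run_engine <- function(network, params, protocol, settings, seed, stochastic) {
  stopifnot(inherits(network, "sb_network"), inherits(protocol, "sb_protocol"),
            inherits(settings, "sb_settings"))
  spec <- compile_spec(network, params)
  dt <- settings$dt
  k1 <- (protocol$t_stress - protocol$t_burnin_start) / dt
  k2 <- (protocol$t_end - protocol$t_burnin_start) / dt
  if (abs(k1 - round(k1)) > 1e-6 || abs(k2 - round(k2)) > 1e-6)
    stop("stress and end times must fall on the dt grid")
  x0 <- start_state(network, params, settings)
  out_every <- as.integer(round(settings$output_dt / dt))
  if (!is.null(seed)) set.seed(seed)
  res <- cle_simulate_cpp(spec, x0, protocol$t_burnin_start, protocol$t_stress,
                          protocol$t_end, dt, out_every,
                          stress_vector(network, params), stochastic,
                          settings$newton_tol, settings$newton_max)
  nout <- nrow(res$x)
  times <- protocol$t_burnin_start + (seq_len(nout) - 1) * settings$output_dt
  make_trajectory(times, res$x, network, params, protocol, settings,
                  engine = if (stochastic) "cle" else "ode", seed = seed,
                  diagnostics = list(newton_iters = res$newton_iters,
                                     halvings = res$halvings))
}

#' Simulate the sigma-B circuit
#'
#' `simulate_ode()` integrates the deterministic reaction-rate equations;
#' `simulate_cle()` integrates the chemical Langevin equation
#' `dx_i = sum_j v_ij a_j dt + sum_j s_j v_ij sqrt(|a_j|) dW_j`, where the
#' noise scale `s_j` is `eta` for core reactions and `eta_amp` for the
#' upstream phosphatase-switching reactions; `simulate_ssa()` runs Gillespie's
#' direct method on integer molecule counts (same numerical rate values read
#' in molecule units; no volume conversion). All three start from the
#' pre-stress initial condition, relax through the burn-in, apply the
#' phosphatase stress step at `t_stress`, and run to `t_end`.
#'
#' Both the ODE and CLE paths use the same fixed-step drift-implicit
#' Euler-Maruyama integrator, so the CLE at `eta = eta_amp = 0` reproduces
#' the ODE path to solver tolerance. Negative excursions of species under
#' Langevin noise are tolerated; only the square-root arguments of the noise
#' terms are absolute-valued.
#'
#' @param network an [sb_network][core_network] object.
#' @param params an [sb_params()] object.
#' @param protocol a [stress_protocol()].
#' @param settings a [sim_settings()].
#' @param seed integer seed fixing the stochastic path.
#' @return An `sb_trajectory`: matrix with column `time_h` followed by one
#'   column per species, with the engine, seed, parameter snapshot, protocol
#'   and solver diagnostics stored as attributes.
#' @examples
#' net <- core_network()
#' tr <- simulate_ode(net, sb_params(), stress_protocol(t_end = 20))
#' max(tr[, "sigB"])
#' @export
simulate_ode <- function(network, params = sb_params(),
                         protocol = stress_protocol(),
                         settings = sim_settings()) {
  run_engine(network, params, protocol, settings, seed = NULL,
             stochastic = FALSE)
}

#' @rdname simulate_ode
#' @export
simulate_cle <- function(network, params = sb_params(),
                         protocol = stress_protocol(),
                         settings = sim_settings(), seed = 1L) {
  run_engine(network, params, protocol, settings, seed = seed,
             stochastic = TRUE)
}

#' @rdname simulate_ode
#' @export
simulate_ssa <- function(network, params = sb_params(),
                         protocol = stress_protocol(),
                         settings = sim_settings(), seed = 1L) {
  stopifnot(inherits(network, "sb_network"), inherits(protocol, "sb_protocol"))
  spec <- compile_spec(network, params)
  x0 <- round(init_state(network, params))
  times <- seq(protocol$t_burnin_start, protocol$t_end, by = settings$output_dt)
  sa <- round(stress_vector(network, params))
  set.seed(seed)
  x <- ssa_simulate_cpp(spec, x0, protocol$t_burnin_start, protocol$t_stress,
                        protocol$t_end, times, sa)
  make_trajectory(times, x, network, params, protocol, settings,
                  engine = "ssa", seed = seed)
}

make_trajectory <- function(times, x, network, params, protocol, settings,
                            engine, seed, diagnostics = NULL) {
  colnames(x) <- network$species
  out <- cbind(time_h = times, x)
  structure(out, class = c("sb_trajectory", class(out)),
            engine = engine, seed = seed, model = network$model,
            params = params, protocol = protocol, settings = settings,
            diagnostics = diagnostics)
}

#' Simulate a seeded ensemble
#'
#' Runs `n` independent trajectories with seeds `base_seed, base_seed + 1,
#' ..., base_seed + n - 1` under shared settings. Members are independent, so
#' the result does not depend on evaluation order.
#'
#' @inheritParams simulate_ode
#' @param engine `"cle"` (default), `"ode"` or `"ssa"`.
#' @param n number of members.
#' @param base_seed seed of the first member.
#' @return An `sb_ensemble`: list of `sb_trajectory` objects.
#' @export
simulate_ensemble <- function(network, params = sb_params(),
                              protocol = stress_protocol(),
                              settings = sim_settings(),
                              engine = c("cle", "ode", "ssa"),
                              n = 50, base_seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(n >= 1)
  sim <- switch(engine, cle = simulate_cle, ssa = simulate_ssa,
                ode = function(network, params, protocol, settings, seed)
                  simulate_ode(network, params, protocol, settings))
  members <- lapply(seq_len(n) - 1L, function(i)
    sim(network, params, protocol, settings, seed = base_seed + i))
  structure(members, class = "sb_ensemble",
            engine = engine, base_seed = base_seed, model = network$model,
            params = params, protocol = protocol, settings = settings)
}

#' Pointwise ensemble mean of a species
#'
#' @param ensemble an `sb_ensemble`.
#' @param species species name (default `"sigB"`).
#' @return Matrix with columns `time_h` and `mean`.
#' @export
ensemble_mean <- function(ensemble, species = "sigB") {
  stopifnot(inherits(ensemble, "sb_ensemble"), length(ensemble) >= 1)
  t0 <- ensemble[[1]][, "time_h"]
  vals <- vapply(ensemble, function(tr) {
    if (!isTRUE(all.equal(tr[, "time_h"], t0)))
      stop("ensemble members have mismatched time grids")
    tr[, species]
  }, numeric(length(t0)))
  cbind(time_h = t0, mean = rowMeans(vals))
}

#' @export
print.sb_trajectory <- function(x, ...) {
  cat("sb_trajectory (", attr(x, "engine"), " engine, ",
      attr(x, "model"), " model): ", nrow(x), " samples, t in [",
      min(x[, "time_h"]), ", ", max(x[, "time_h"]), "] h\n", sep = "")
  if (!is.null(attr(x, "seed"))) cat("  seed:", attr(x, "seed"), "\n")
  cat("  final state:\n")
  print(round(x[nrow(x), -1], 5))
  invisible(x)
}

#' @export
plot.sb_trajectory <- function(x, species = "sigB", ...) {
  graphics::plot(x[, "time_h"], x[, species], type = "l",
                 xlab = "time (h)", ylab = paste0("[", species, "]"), ...)
  graphics::abline(v = attr(x, "protocol")$t_stress, col = 2, lty = 2)
  invisible(x)
}

#' @export
print.sb_ensemble <- function(x, ...) {
  cat("sb_ensemble: ", length(x), " members (", attr(x, "engine"),
      " engine, ", attr(x, "model"), " model), base seed ",
      attr(x, "base_seed"), "\n", sep = "")
  invisible(x)
}

#' @export
plot.sb_ensemble <- function(x, species = "sigB", members = seq_len(min(4, length(x))), ...) {
  tm <- x[[1]][, "time_h"]
  ys <- sapply(x[members], function(tr) tr[, species])
  graphics::matplot(tm, ys, type = "l", lty = 1,
                    xlab = "time (h)", ylab = paste0("[", species, "]"), ...)
  graphics::abline(v = attr(x, "protocol")$t_stress, col = 2, lty = 2)
  invisible(x)
}
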