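#' Build the core sigma-B reaction network
#'
#' Constructs the 10-species, 27-reaction chemical reaction network of the
#' core sigma-B partner-switching circuit: sigma-B operon production of
#' sigma-B, RsbW (W) and RsbV (V); W dimerisation; complex formation between
#' the W dimer, V, sigma-B and the phosphatase P; the two partner-switching
#' exchange reactions; complex dissociations; RsbV phosphorylation by the W
#' dimer kinase and dephosphorylation by P; and first-order
#' degradation/dilution of every non-phosphatase species (degradation of the
#' P-VP complex releases P, so total phosphatase is conserved).
#'
#' The operon production propensity is `f(s) = v0 * (1 + F*s)/(K + s)` with
#' `s = [sigB]` (the default `"ratio"` form; the behaviour of the circuit
#' under this form matches the published steady-state stability structure of
#' the model, see the methods vignette). `production_form = "offset"` selects
#' the alternative reading `v0 * (1 + F*s/(K+s))`, whose basal rate is
#' exactly `v0`. W, V production use the same form scaled by `lambda_W`,
#' `lambda_V`. Dimerisation uses the combinatorial propensity `kBw*[W]^2/2`
#' (`kBw*W*(W-1)/2` in molecule-count mode).
#'
#' @param params an [sb_params()] object; validated on entry.
#' @param production_form `"ratio"` (default) or `"offset"`; see Details.
#' @return An object of class `sb_network` with elements `model`, `species`,
#'   `S` (species-by-reaction stoichiometry matrix), `rxn` (per-reaction
#'   table: description, kinetic type, rate parameter, reactant indices,
#'   noise group) and `production_form`.
#' @examples
#' net <- core_network()
#' ncol(net$S)      # 27 reactions
#' length(net$species)  # 10 species
#' @export
core_network <- function(params = sb_params(), production_form = c("ratio", "offset")) {
  validate_params(params)
  production_form <- match.arg(production_form)
  species <- c("sigB", "W", "W2", "W2sigB", "W2V", "W2V2", "V", "VP", "P", "PVP")
  rxn <- rbind(
    rx("production sigB",   "production", NA, prod = c(sigB = 1)),
    rx("production W",      "production", "lambda_W", prod = c(W = 1)),
    rx("production V",      "production", "lambda_V", prod = c(V = 1)),
    rx("dimerisation 2W -> W2",       "dimer", "kBw", r1 = "W", react = c(W = 2), prod = c(W2 = 1)),
    rx("binding W2 + V -> W2V",       "mass2", "kB1", r1 = "W2", r2 = "V", react = c(W2 = 1, V = 1), prod = c(W2V = 1)),
    rx("binding W2V + V -> W2V2",     "mass2", "kB2", r1 = "W2V", r2 = "V", react = c(W2V = 1, V = 1), prod = c(W2V2 = 1)),
    rx("binding W2 + sigB -> W2sigB", "mass2", "kB3", r1 = "W2", r2 = "sigB", react = c(W2 = 1, sigB = 1), prod = c(W2sigB = 1)),
    rx("binding P + VP -> PVP",       "mass2", "kB5", r1 = "P", r2 = "VP", react = c(P = 1, VP = 1), prod = c(PVP = 1)),
    rx("switch W2sigB + V -> W2V + sigB", "mass2", "kB4", r1 = "W2sigB", r2 = "V",
       react = c(W2sigB = 1, V = 1), prod = c(W2V = 1, sigB = 1)),
    rx("switch W2V + sigB -> W2sigB + V", "mass2", "kD4", r1 = "W2V", r2 = "sigB",
       react = c(W2V = 1, sigB = 1), prod = c(W2sigB = 1, V = 1)),
    rx("dissociation W2 -> 2W",        "mass1", "kDw", r1 = "W2", react = c(W2 = 1), prod = c(W = 2)),
    rx("dissociation W2V -> W2 + V",   "mass1", "kD1", r1 = "W2V", react = c(W2V = 1), prod = c(W2 = 1, V = 1)),
    rx("dissociation W2V2 -> W2V + V", "mass1", "kD2", r1 = "W2V2", react = c(W2V2 = 1), prod = c(W2V = 1, V = 1)),
    rx("dissociation W2sigB -> W2 + sigB", "mass1", "kD3", r1 = "W2sigB", react = c(W2sigB = 1), prod = c(W2 = 1, sigB = 1)),
    rx("dissociation PVP -> P + VP",   "mass1", "kD5", r1 = "PVP", react = c(PVP = 1), prod = c(P = 1, VP = 1)),
    rx("phosphorylation W2V -> W2 + VP",    "mass1", "kK1", r1 = "W2V", react = c(W2V = 1), prod = c(W2 = 1, VP = 1)),
    rx("phosphorylation W2V2 -> W2V + VP",  "mass1", "kK2", r1 = "W2V2", react = c(W2V2 = 1), prod = c(W2V = 1, VP = 1)),
    rx("dephosphorylation PVP -> P + V",    "mass1", "kP", r1 = "PVP", react = c(PVP = 1), prod = c(P = 1, V = 1)),
    rx("degradation sigB",   "mass1", "kdeg", r1 = "sigB",   react = c(sigB = 1)),
    rx("degradation W",      "mass1", "kdeg", r1 = "W",      react = c(W = 1)),
    rx("degradation W2",     "mass1", "kdeg", r1 = "W2",     react = c(W2 = 1)),
    rx("degradation W2sigB", "mass1", "kdeg", r1 = "W2sigB", react = c(W2sigB = 1)),
    rx("degradation W2V",    "mass1", "kdeg", r1 = "W2V",    react = c(W2V = 1)),
    rx("degradation W2V2",   "mass1", "kdeg", r1 = "W2V2",   react = c(W2V2 = 1)),
    rx("degradation V",      "mass1", "kdeg", r1 = "V",      react = c(V = 1)),
    rx("degradation VP",     "mass1", "kdeg", r1 = "VP",     react = c(VP = 1)),
    rx("degradation PVP -> P", "mass1", "kdeg", r1 = "PVP",  react = c(PVP = 1), prod = c(P = 1))
  )
  build_network("core", species, rxn, production_form)
}

#' Build the upstream-noise extension of the sigma-B network
#'
#' Adds to the core network an inactive phosphatase species `PI` and the three
#' phosphatase state-switching reactions: activation `PI -> P`, deactivation
#' `P -> PI`, and deactivation of complexed phosphatase `PVP -> PI + VP`, all
#' at rate `eta_freq`. These three reactions carry the noise group
#' `"upstream"`, so their Langevin noise terms are scaled by `eta_amp` rather
#' than the core amplitude `eta`; `eta_freq` leaves the deterministic
#' dynamics of total phosphatase unchanged but sets the time scale (and hence
#' frequency content) of the upstream fluctuations.
#'
#' @inheritParams core_network
#' @return An `sb_network` with 11 species and 30 reactions.
#' @examples
#' net <- modified_network()
#' sum(net$rxn$noise_group == "upstream")  # 3
#' @export
modified_network <- function(params = sb_params(), production_form = c("ratio", "offset")) {
  validate_params(params)
  if (is.null(params$eta_amp) || is.null(params$eta_freq))
    stop("the modified model requires parameters 'eta_amp' and 'eta_freq'")
  production_form <- match.arg(production_form)
  base <- core_network(params, production_form)
  species <- c(base$species, "PI")
  extra <- rbind(
    rx("activation PI -> P",        "mass1", "eta_freq", r1 = "PI",  react = c(PI = 1),  prod = c(P = 1),  group = "upstream"),
    rx("deactivation P -> PI",      "mass1", "eta_freq", r1 = "P",   react = c(P = 1),   prod = c(PI = 1), group = "upstream"),
    rx("deactivation PVP -> PI + VP", "mass1", "eta_freq", r1 = "PVP", react = c(PVP = 1), prod = c(PI = 1, VP = 1), group = "upstream")
  )
  rxn <- rbind(base$rxn, extra)
  build_network("modified", species, rxn, production_form)
}

# one reaction row; `react`/`prod` are named stoichiometries
rx <- function(description, type, rate_param = NA_character_,
               r1 = NA_character_, r2 = NA_character_,
               react = numeric(0), prod = numeric(0), group = "core") {
  data.frame(description = description, type = type, rate_param = rate_param,
             r1 = r1, r2 = r2,
             reactants = I(list(react)), products = I(list(prod)),
             noise_group = group, stringsAsFactors = FALSE)
}

build_network <- function(model, species, rxn, production_form) {
  n <- length(species)
  m <- nrow(rxn)
  S <- matrix(0L, n, m, dimnames = list(species, NULL))
  for (j in seq_len(m)) {
    re <- rxn$reactants[[j]]
    pr <- rxn$products[[j]]
    if (length(re)) S[names(re), j] <- S[names(re), j] - as.integer(re)
    if (length(pr)) S[names(pr), j] <- S[names(pr), j] + as.integer(pr)
  }
  structure(list(model = model, species = species, S = S, rxn = rxn,
                 production_form = production_form),
            class = "sb_network")
}

#' @export
print.sb_network <- function(x, ...) {
  cat("sb_network: ", x$model, " sigma-B circuit model\n", sep = "")
  cat("  ", length(x$species), " species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$rxn), " reactions (", sum(x$rxn$noise_group == "upstream"),
      " upstream noise group)\n", sep = "")
  cat("  production form: ", x$production_form, "\n", sep = "")
  invisible(x)
}

# operon production rate f([sigB]) and its derivative
production_rate <- function(s, params, form) {
  if (form == "offset") params$v0 * (1 + params$F * s / (params$K + s))
  else params$v0 * (1 + params$F * s) / (params$K + s)
}

production_rate_deriv <- function(s, params, form) {
  if (form == "offset") params$v0 * params$F * params$K / (params$K + s)^2
  else params$v0 * (params$F * params$K - 1) / (params$K + s)^2
}

#' Evaluate per-reaction propensities
#'
#' Mass-action propensities for every reaction of the network at a given
#' state. Bimolecular reactions use `k*[X]*[Y]`, dimerisation the
#' combinatorial `k*[X]^2/2` (continuous mode) or `k*X*(X-1)/2` (discrete
#' mode), production the operon rate `f([sigB])` times `1`, `lambda_W` or
#' `lambda_V`.
#'
#' @param network an `sb_network`.
#' @param state named numeric vector of species amounts (one per species).
#' @param params an [sb_params()] object.
#' @param strict if `TRUE`, negative amounts are rejected; if `FALSE`
#'   (chemical-Langevin convention) they are tolerated and propensities are
#'   evaluated as-is (possibly negative in intermediate algebra; the Langevin
#'   noise term takes absolute values before the square root).
#' @param discrete if `TRUE`, use molecule-count combinatorics for the
#'   dimerisation propensity.
#' @return Numeric vector of length `nrow(network$rxn)`.
#' @examples
#' net <- core_network()
#' st <- init_state(net, sb_params())
#' propensities(net, st, sb_params())
#' @export
propensities <- function(network, state, params, strict = FALSE, discrete = FALSE) {
  stopifnot(inherits(network, "sb_network"))
  state <- as_state(network, state)
  if (strict && any(state < 0))
    stop("negative species amount(s) in strict mode: ",
         paste(network$species[state < 0], collapse = ", "))
  rxn <- network$rxn
  a <- numeric(nrow(rxn))
  f <- production_rate(state[["sigB"]], params, network$production_form)
  for (j in seq_len(nrow(rxn))) {
    k <- if (is.na(rxn$rate_param[j])) 1 else params[[rxn$rate_param[j]]]
    a[j] <- switch(rxn$type[j],
      production = k * f,
      mass1 = k * state[[rxn$r1[j]]],
      mass2 = k * state[[rxn$r1[j]]] * state[[rxn$r2[j]]],
      dimer = if (discrete) k * state[[rxn$r1[j]]] * (state[[rxn$r1[j]]] - 1) / 2
              else k * state[[rxn$r1[j]]]^2 / 2,
      stop("unknown reaction type"))
  }
  a
}

#' Deterministic drift and its Jacobian
#'
#' `drift()` returns the reaction-rate-equation right-hand side
#' `S %*% a(state)`; `drift_jacobian()` its analytic Jacobian with respect to
#' the species amounts. Used by the deterministic/implicit integrators and the
#' steady-state stability analysis.
#'
#' @inheritParams propensities
#' @return `drift()`: named numeric vector; `drift_jacobian()`: square matrix.
#' @export
drift <- function(network, state, params) {
  a <- propensities(network, state, params)
  as.numeric(network$S %*% a)
}

#' @rdname drift
#' @export
drift_jacobian <- function(network, state, params) {
  state <- as_state(network, state)
  rxn <- network$rxn
  n <- length(network$species)
  m <- nrow(rxn)
  # da[j]/dx[i]
  dA <- matrix(0, m, n, dimnames = list(NULL, network$species))
  fp <- production_rate_deriv(state[["sigB"]], params, network$production_form)
  for (j in seq_len(m)) {
    k <- if (is.na(rxn$rate_param[j])) 1 else params[[rxn$rate_param[j]]]
    switch(rxn$type[j],
      production = { dA[j, "sigB"] <- k * fp },
      mass1 = { dA[j, rxn$r1[j]] <- k },
      mass2 = {
        dA[j, rxn$r1[j]] <- dA[j, rxn$r1[j]] + k * state[[rxn$r2[j]]]
        dA[j, rxn$r2[j]] <- dA[j, rxn$r2[j]] + k * state[[rxn$r1[j]]]
      },
      dimer = { dA[j, rxn$r1[j]] <- k * state[[rxn$r1[j]]] })
  }
  J <- network$S %*% dA
  dimnames(J) <- list(network$species, network$species)
  J
}

#' Stress protocol
#'
#' Timing of a stress-response simulation: burn-in start, stress onset and
#' end time (hours). Simulations start `t_burnin_start` (default -10 h), the
#' phosphatase step is applied at `t_stress` (default 0) and the run ends at
#' `t_end` (default 200 h).
#'
#' @param t_burnin_start,t_stress,t_end times in hours.
#' @return An object of class `sb_protocol`.
#' @export
stress_protocol <- function(t_burnin_start = -10, t_stress = 0, t_end = 200) {
  if (!(t_burnin_start < t_stress && t_stress < t_end))
    stop("require t_burnin_start < t_stress < t_end")
  structure(list(t_burnin_start = t_burnin_start, t_stress = t_stress,
                 t_end = t_end), class = "sb_protocol")
}

#' Initial state and stress step
#'
#' `init_state()` returns the pre-stress initial condition: every species at
#' zero except the free phosphatase at `p_init` (in the modified model both
#' `P` and `PI` start at `p_init`). `apply_stress()` applies the stress step:
#' the core model raises free `[P]` by `p_stress - p_init`; the modified model
#' raises both `[P]` and `[PI]` by `p_stress - p_init` (total phosphatase
#' becomes `2*p_stress` up to whatever is bound in `PVP`). All other species
#' are unchanged.
#'
#' @inheritParams propensities
#' @return A named numeric state vector.
#' @examples
#' net <- core_network()
#' p <- sb_params(p_stress = 0.4)
#' st <- apply_stress(init_state(net, p), net, p)
#' st[["P"]]  # 0.4
#' @export
init_state <- function(network, params) {
  st <- stats::setNames(numeric(length(network$species)), network$species)
  st[["P"]] <- params$p_init
  if (network$model == "modified") st[["PI"]] <- params$p_init
  st
}

#' @rdname init_state
#' @param state named numeric state vector.
#' @export
apply_stress <- function(state, network, params) {
  state <- as_state(network, state)
  dp <- params$p_stress - params$p_init
  if (dp < 0)
    message("apply_stress: p_stress < p_init (stress removal); proceeding")
  state[["P"]] <- state[["P"]] + dp
  if (network$model == "modified") state[["PI"]] <- state[["PI"]] + dp
  state
}

as_state <- function(network, state) {
  sp <- network$species
  if (is.null(names(state))) {
    if (length(state) != length(sp))
      stop("state must have one amount per species (", length(sp), ")")
    names(state) <- sp
  } else {
    missing <- setdiff(sp, names(state))
    if (length(missing))
      stop("state is missing species: ", paste(missing, collapse = ", "))
    state <- state[sp]
  }
  if (any(!is.finite(state))) stop("state contains non-finite amounts")
  state
}
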