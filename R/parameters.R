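#' Parameter set for the sigma-B circuit model
#'
#' Constructs the full parameter set of the sigma-B partner-switching circuit.
#' Defaults are the canonical values of the underlying chemical reaction
#' network model: operon production (`v0`, `F`, `K`), the relative production
#' rates of the anti-sigma factor RsbW (`lambda_W`) and anti-anti-sigma factor
#' RsbV (`lambda_V`), binding/dissociation/partner-switching rate constants,
#' the RsbV phosphorylation (`kK1`, `kK2`) and dephosphorylation (`kP`) rates,
#' dilution (`kdeg`), the pre- and post-stress phosphatase levels (`p_init`,
#' `p_stress`), and the noise amplitude `eta` of the chemical Langevin
#' equation. The upstream-noise model extension adds `eta_amp` (upstream noise
#' amplitude) and `eta_freq` (phosphatase activation/deactivation switching
#' rate, which sets the frequency of upstream fluctuations without changing
#' the deterministic dynamics).
#'
#' Instead of `p_stress` and `kP`, the substituted pair may be given:
#' `p_prod = p_stress * kP` (total RsbV dephosphorylation efficiency) and
#' `p_frac = p_stress / kP`. Supplying a substituted value together with an
#' explicit `p_stress`/`kP` override is rejected as over-determined.
#'
#' @param ... named overrides of the default values listed above.
#' @param p_prod,p_frac optional substituted upstream parameters; if either is
#'   given both must be, and `p_stress`/`kP` must not be overridden directly.
#'
#' @return An object of class `sb_params`: a named list of numeric scalars
#'   with 24 core entries plus `eta_amp` and `eta_freq`.
#'
#' @details Units: concentrations in uM, time in hours; bimolecular rate
#'   constants in 1/(uM hr), unimolecular in 1/hr; `F`, `lambda_W`,
#'   `lambda_V`, `eta`, `eta_amp` dimensionless; `eta_freq` in 1/hr. For
#'   molecule-count (SSA) simulations the same numerical values are used with
#'   "uM" read as molecule counts; no volume conversion is applied.
#'
#' @examples
#' p <- sb_params(kK2 = 7, eta = 0.025)
#' p2 <- sb_params(p_prod = 72, p_frac = 100)
#' all.equal(p2$p_stress * p2$kP, 72)
#' @export
sb_params <- function(..., p_prod = NULL, p_frac = NULL) {
  defaults <- list(
    v0 = 0.4, F = 30, K = 0.2,
    lambda_W = 4, lambda_V = 4.5,
    kBw = 3600, kDw = 18,
    kB1 = 3600, kB2 = 3600, kB3 = 3600, kB4 = 1800, kB5 = 3600,
    kD1 = 18, kD2 = 18, kD3 = 18, kD4 = 1800, kD5 = 18,
    kK1 = 36, kK2 = 36, kP = 180, kdeg = 0.7,
    p_init = 0.001, p_stress = 0.4, eta = 0.025,
    eta_amp = 0.05, eta_freq = 1
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (!is.null(p_prod) || !is.null(p_frac)) {
    if (is.null(p_prod) || is.null(p_frac))
      stop("p_prod and p_frac must be supplied together")
    if (any(c("p_stress", "kP") %in% names(over)))
      stop("over-determined: give either (p_stress, kP) or (p_prod, p_frac), not both")
    if (p_prod <= 0 || p_frac <= 0)
      stop("p_prod and p_frac must be strictly positive")
    sub <- substitution_to_rates(p_prod, p_frac)
    over$p_stress <- sub[["p_stress"]]
    over$kP <- sub[["kP"]]
  }
  p <- utils::modifyList(defaults, lapply(over, as.numeric))
  p <- structure(p, class = "sb_params")
  validate_params(p)
  p
}

#' @rdname sb_params
#' @param params an `sb_params` object.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "sb_params")) stop("not an sb_params object")
  positive <- c("v0", "F", "K", "lambda_W", "lambda_V",
                "kBw", "kDw", "kB1", "kB2", "kB3", "kB4", "kB5",
                "kD1", "kD2", "kD3", "kD4", "kD5",
                "kK1", "kK2", "kP", "kdeg")
  nonneg <- c("p_init", "p_stress", "eta", "eta_amp", "eta_freq")
  for (nm in c(positive, nonneg)) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  for (nm in positive)
    if (params[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  for (nm in nonneg)
    if (params[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  invisible(params)
}

#' Substituted upstream parameters
#'
#' `param_substitution()` maps `(p_stress, kP)` to the substituted pair
#' `(p_prod, p_frac)`; `substitution_to_rates()` inverts the map,
#' `p_stress = sqrt(p_prod * p_frac)`, `kP = sqrt(p_prod / p_frac)`.
#' The round trip is the identity to machine precision.
#'
#' @param params an `sb_params` object.
#' @return A named numeric vector.
#' @examples
#' s <- param_substitution(sb_params(p_stress = 0.4, kP = 180))
#' substitution_to_rates(s[["p_prod"]], s[["p_frac"]])
#' @export
param_substitution <- function(params) {
  validate_params(params)
  c(p_prod = params$p_stress * params$kP,
    p_frac = params$p_stress / params$kP)
}

#' @rdname param_substitution
#' @param p_prod,p_frac substituted values (`p_stress * kP`, `p_stress / kP`).
#' @export
substitution_to_rates <- function(p_prod, p_frac) {
  stopifnot(is.numeric(p_prod), is.numeric(p_frac), p_prod > 0, p_frac > 0)
  c(p_stress = sqrt(p_prod * p_frac), kP = sqrt(p_prod / p_frac))
}

#' @export
print.sb_params <- function(x, ...) {
  cat("sigma-B circuit parameter set\n")
  core <- setdiff(names(x), c("eta_amp", "eta_freq"))
  vals <- unlist(x[core])
  cat("  core (", length(core), " parameters):\n", sep = "")
  print(vals)
  cat("  upstream-noise extension: eta_amp = ", x$eta_amp,
      ", eta_freq = ", x$eta_freq, "\n", sep = "")
  sub <- param_substitution(x)
  cat("  substitution: p_prod = ", format(sub[["p_prod"]]),
      ", p_frac = ", format(sub[["p_frac"]]), "\n", sep = "")
  invisible(x)
}

# names of the 24 canonical core-model parameters, in table order
core_param_names <- function() {
  c("v0", "F", "K", "lambda_W", "lambda_V",
    "kBw", "kDw", "kB1", "kB2", "kB3", "kB4", "kB5",
    "kD1", "kD2", "kD3", "kD4", "kD5",
    "kK1", "kK2", "kP", "kdeg", "p_init", "p_stress", "eta")
}
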