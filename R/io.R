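#' Read and write parameter configuration files
#'
#' Parameters are serialised as a flat key-value map in YAML or JSON using
#' the canonical parameter names (`v0`, `F`, `K`, `lambda_W`, ..., `p_init`,
#' `p_stress`, `eta`, `eta_amp`, `eta_freq`). A config may instead give the
#' substituted pair `p_prod`/`p_frac`; giving the substituted pair together
#' with `p_stress` or `kP` is rejected as over-determined, and unknown keys
#' are rejected by name. An empty config yields the default parameter set.
#'
#' @param path file path; format inferred from the extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `read_params()`: an [sb_params()]; `write_params()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(sb_params(kK2 = 7), f)
#' identical(read_params(f), sb_params(kK2 = 7))
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- switch(config_format(path),
                 yaml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) vals <- as.list(vals)
  known <- c(names(sb_params()), "p_prod", "p_frac")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad))
    stop("config key(s) not finite numeric scalars: ",
         paste(bad, collapse = ", "))
  sub <- vals[c("p_prod", "p_frac")]
  vals <- vals[setdiff(names(vals), c("p_prod", "p_frac"))]
  if (!is.null(sub$p_prod) || !is.null(sub$p_frac)) {
    if (any(c("p_stress", "kP") %in% names(vals)))
      stop("over-determined config: give (p_stress, kP) or (p_prod, p_frac), not both")
    return(do.call(sb_params, c(vals, list(p_prod = sub$p_prod,
                                           p_frac = sub$p_frac))))
  }
  do.call(sb_params, vals)
}

#' @rdname read_params
#' @param params an [sb_params()] object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  vals <- unclass(params)
  switch(config_format(path),
         yaml = yaml::write_yaml(vals, path),
         json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                     digits = NA))
  invisible(path)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else stop("unsupported config format: .", ext, " (use .yaml or .json)")
}

#' Read and write trajectory CSV files
#'
#' Trajectories are stored as plain CSV with column `time_h` followed by one
#' column per species.
#'
#' @param trajectory an `sb_trajectory`.
#' @param path file path.
#' @return `write_trajectory()`: `path`, invisibly; `read_trajectory()`: an
#'   `sb_trajectory` matrix (engine tag `"file"`; simulation attributes are
#'   not round-tripped).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(unclass(trajectory)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) stop("not a trajectory file (no time_h column)")
  m <- as.matrix(df)
  structure(m, class = c("sb_trajectory", class(m)),
            engine = "file", seed = NULL, model = NULL, params = NULL,
            protocol = NULL, settings = NULL, diagnostics = NULL)
}

#' Write an ensemble with a JSON manifest
#'
#' Writes one CSV per member plus `manifest.json` recording the engine,
#' model, seeds, parameter snapshot and stress protocol — enough to
#' regenerate every member.
#'
#' @param ensemble an `sb_ensemble`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "sb_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(ensemble))
  for (i in seq_along(ensemble)) {
    files[i] <- sprintf("member_%03d.csv", i)
    write_trajectory(ensemble[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    engine = attr(ensemble, "engine"), model = attr(ensemble, "model"),
    n = length(ensemble), base_seed = attr(ensemble, "base_seed"),
    seeds = vapply(ensemble, function(tr) as.integer(attr(tr, "seed") %||% NA),
                   integer(1)),
    params = unclass(attr(ensemble, "params")),
    protocol = unclass(attr(ensemble, "protocol")),
    settings = unclass(attr(ensemble, "settings")),
    files = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  members <- lapply(manifest$files, function(f)
    read_trajectory(file.path(dir, f)))
  structure(members, class = "sb_ensemble",
            engine = manifest$engine, base_seed = manifest$base_seed,
            model = manifest$model, params = manifest$params,
            protocol = manifest$protocol, settings = manifest$settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
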