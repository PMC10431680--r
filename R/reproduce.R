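#' Run a bundled circuit experiment
#'
#' Runs one of the package's standard simulation/scan experiments and writes
#' its outputs (trajectory CSVs, scan tables, stability branches) plus a
#' JSON manifest to `out_dir`. The `"desk"` preset uses reduced ensemble
#' sizes and grid densities so every experiment completes in minutes on one
#' CPU; `"paper"` uses publication-scale n (hours of compute). Presets never
#' change the model or the measures, only n and grid density.
#'
#' Supported names:
#' * `"noise_response"`: ensemble-mean sigma-B response at default
#'   parameters for a range of noise amplitudes.
#' * `"pulsing_optimum"`: sample trajectories and behaviour scores at the
#'   stochastic-pulsing-optimised parameter set (kK2 = 9, eta = 0.06), with
#'   the stress level maximising stochastic pulsing.
#' * `"stress_ladder"`: single trajectories at a ladder of p_prod values
#'   spanning the no-response to sustained-activity transition at the
#'   (kK2, eta) = (7, 0.025) base set (p_prod varied through the stress
#'   level at the canonical dephosphorylation rate), plus ensemble
#'   classifications.
#' * `"kinase_branches"`: stability branches over a tenfold kK2 sweep at
#'   three stress levels.
#' * `"stress_branch"`: stability branch over p_stress in (0.1, 10) uM at
#'   default parameters.
#' * `"behaviour_flip"`: behaviour scores bracketing the
#'   single-pulse/stochastic-pulsing boundary at (kK2, eta) = (7, 0.025).
#' * `"ladder_branch"`: deterministic stability branch along p_prod at the
#'   stress-ladder base set.
#' * `"ssa_ladder"`: Gillespie trajectories over increasing stress
#'   (molecule units).
#'
#' @param name experiment name (see above).
#' @param preset `"desk"` (default) or `"paper"`.
#' @param seed root seed.
#' @param out_dir output directory.
#' @return The manifest (a list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_experiment <- function(name, preset = c("desk", "paper"), seed = 1L,
                           out_dir = file.path("experiments", name)) {
  preset <- match.arg(preset)
  supported <- c("noise_response", "pulsing_optimum", "stress_ladder",
                 "kinase_branches", "stress_branch", "behaviour_flip",
                 "ladder_branch", "ssa_ladder")
  if (!name %in% supported)
    stop("unsupported experiment '", name, "'; available: ",
         paste(supported, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- if (preset == "desk") 20L else 150L
  manifest <- list(experiment = name, preset = preset, seed = seed, n = n,
                   outputs = character(0))
  add <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  if (name == "noise_response") {
    etas <- c(0.01, 0.025, 0.05, 0.1)
    for (eta in etas) {
      p <- sb_params(eta = eta)
      net <- core_network(p)
      e <- simulate_ensemble(net, p, settings = sim_settings(dt = 5e-4),
                             n = n, base_seed = seed)
      em <- ensemble_mean(e)
      f <- sprintf("mean_sigB_eta_%g.csv", eta)
      utils::write.csv(as.data.frame(em), file.path(out_dir, f),
                       row.names = FALSE)
      add(f)
    }
  } else if (name == "pulsing_optimum") {
    p <- sb_params(kK2 = 9, eta = 0.06)
    best <- optimise_stress_for_pulsing(p, n = max(8L, n %/% 2L),
                                        base_seed = seed)
    p$p_stress <- best$p_stress
    net <- core_network(p)
    e <- simulate_ensemble(net, p, settings = sim_settings(dt = 5e-4),
                           n = 4L, base_seed = seed)
    for (i in seq_along(e)) {
      f <- sprintf("sample_%d.csv", i)
      write_trajectory(e[[i]], file.path(out_dir, f)); add(f)
    }
    manifest$p_stress <- best$p_stress
    manifest$scores <- best$scan[, c("p_stress", "M_srp", "M_sp")]
  } else if (name == "stress_ladder") {
    pps <- ladder_p_prod_values()
    labs <- character(length(pps))
    for (i in seq_along(pps)) {
      p <- ladder_base_params(pps[i])
      net <- core_network(p)
      tr <- simulate_cle(net, p, seed = seed + i)
      f <- sprintf("p_prod_%05.0f.csv", pps[i])
      write_trajectory(tr, file.path(out_dir, f)); add(f)
      cls <- classify_response(simulate_ensemble(net, p, n = max(10L, n %/% 2L),
                                                 base_seed = seed + 1000L * i))
      labs[i] <- cls$label
    }
    manifest$p_prod <- pps
    manifest$labels <- labs
  } else if (name == "kinase_branches") {
    for (ps in c(0.05, 0.2, 0.8)) {
      br <- branch_scan("kK2", NULL, sb_params(p_stress = ps),
                        n_points = if (preset == "desk") 25 else 101)
      f <- sprintf("branch_kK2_ps_%g.csv", ps)
      utils::write.csv(as.data.frame(br), file.path(out_dir, f),
                       row.names = FALSE)
      add(f)
    }
  } else if (name == "stress_branch") {
    br <- branch_scan("p_stress", c(0.1, 10), sb_params(),
                      n_points = if (preset == "desk") 25 else 101)
    utils::write.csv(as.data.frame(br), file.path(out_dir, "branch_p_stress.csv"),
                     row.names = FALSE)
    add("branch_p_stress.csv")
    manifest$unstable_intervals <- attr(br, "unstable_intervals")
  } else if (name == "behaviour_flip") {
    for (ps in c(0.24, 0.28)) {
      p <- sb_params(kK2 = 7, eta = 0.025, p_stress = ps)
      net <- core_network(p)
      e <- simulate_ensemble(net, p, n = max(n, 50L), base_seed = seed)
      s <- behaviour_magnitudes(e)
      f <- sprintf("scores_ps_%g.json", ps)
      jsonlite::write_json(list(p_stress = ps, n = s$n,
                                mean_M_srp = s$mean_M_srp,
                                mean_M_sp = s$mean_M_sp,
                                M_srp = s$M_srp, M_sp = s$M_sp),
                           file.path(out_dir, f), auto_unbox = TRUE,
                           digits = NA)
      add(f)
    }
  } else if (name == "ladder_branch") {
    p4 <- ladder_base_params(72)
    br <- branch_scan("p_stress", c(0.1, 3), p4,
                      n_points = if (preset == "desk") 31 else 121)
    df <- as.data.frame(br)
    df$p_prod <- df$value * p4$kP
    utils::write.csv(df, file.path(out_dir, "branch_p_prod.csv"),
                     row.names = FALSE)
    add("branch_p_prod.csv")
    manifest$unstable_intervals <- attr(br, "unstable_intervals")
  } else if (name == "ssa_ladder") {
    for (ps in c(1, 2, 5, 10, 20, 50)) {
      p <- sb_params(p_init = 0, p_stress = ps, kK2 = 7)
      net <- core_network(p)
      tr <- simulate_ssa(net, p, seed = seed)
      f <- sprintf("ssa_ps_%g.csv", ps)
      write_trajectory(tr, file.path(out_dir, f)); add(f)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Base parameter set of the p_prod transition experiments: kK2 = 7,
# eta = 0.025, with p_prod realised by varying p_stress at the canonical
# dephosphorylation rate kP = 180/hr. Stochastic pulsing requires relative
# Langevin noise of order one on the pulse scale, which pins the circuit to
# micromolar concentrations; see the methods vignette.
ladder_base_params <- function(p_prod) {
  sb_params(kK2 = 7, eta = 0.025, p_stress = p_prod / 180)
}

# ladder of p_prod values spanning no-response -> single pulse ->
# stochastic pulsing -> oscillation -> sustained activity under the default
# model form (see the methods vignette for how these were located)
ladder_p_prod_values <- function() c(18, 43.2, 57.6, 90, 270, 540)

#' Pick the stress level maximising stochastic pulsing
#'
#' Two-stage log-spaced p_stress scan at the given parameter set, scoring
#' each level by the ensemble-mean stochastic-pulsing magnitude: a coarse
#' pass over `range` followed by a refinement around the best coarse point
#' (the pulsing optimum is narrow on a log axis). Returns the maximising
#' level and the combined scan table.
#'
#' @param params base [sb_params()] (p_stress is overridden).
#' @param range log-spaced scan interval in uM.
#' @param n_points number of coarse scan points.
#' @param n ensemble size per point.
#' @param base_seed root seed.
#' @param settings [sim_settings()] for the scan ensembles.
#' @param refine number of new points added per refinement round
#'   (0 disables refinement).
#' @param rounds number of refinement rounds; each round brackets the
#'   current optimum with its grid neighbours and subdivides.
#' @return A list with `p_stress`, `score` and `scan` (data frame).
#' @export
optimise_stress_for_pulsing <- function(params, range = c(0.2, 200),
                                        n_points = 10, n = 20,
                                        base_seed = 1L,
                                        settings = sim_settings(dt = 5e-4),
                                        refine = 4, rounds = 2) {
  grid <- exp(seq(log(range[1]), log(range[2]), length.out = n_points))
  sc <- sweep_scan(list(p_stress = grid), params = params, n = n,
                   base_seed = base_seed, settings = settings)
  df <- as.data.frame(sc)
  best <- locate_optimum(df, "M_sp")
  if (refine > 0) {
    for (r in seq_len(rounds)) {
      g <- sort(df$p_stress)
      i <- match(df$p_stress[best$index], g)
      lo <- g[max(1, i - 1)]
      hi <- g[min(length(g), i + 1)]
      g2 <- exp(seq(log(lo), log(hi), length.out = refine + 2))
      g2 <- setdiff(signif(g2, 10), signif(g, 10))
      if (!length(g2)) break
      sc2 <- sweep_scan(list(p_stress = g2), params = params, n = n,
                        base_seed = base_seed + 500000L * r,
                        settings = settings)
      df <- rbind(df, as.data.frame(sc2))
      df <- df[order(df$p_stress), ]
      rownames(df) <- NULL
      best <- locate_optimum(df, "M_sp")
    }
  }
  list(p_stress = df$p_stress[best$index], score = best$score, scan = df)
}
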