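net <- core_network()
params <- sb_params()

test_that("a pure-decay subsystem follows the exponential solution", {
  # zero every rate except first-order sigma-B degradation; the implicit
  # integrator is first order, so a small step is needed for 1e-6 accuracy
  spec <- sigbpulse:::compile_spec(net, params)
  spec$rate[] <- 0
  spec$rate[which(net$rxn$description == "degradation sigB")] <- 0.7
  x0 <- numeric(10); x0[1] <- 1
  res <- sigbpulse:::cle_simulate_cpp(spec, x0, 0, 1, 2, 5e-6, 2000L,
                                      numeric(10), FALSE, 1e-12, 20L)
  tt <- seq(0, 2, by = 0.01)
  expect_lt(max(abs(res$x[, 1] - exp(-0.7 * tt))), 1e-6)
})

test_that("the noise-free Langevin path equals the ODE path", {
  pr <- stress_protocol(t_end = 20)
  p0 <- sb_params(eta = 0)
  ode <- simulate_ode(net, p0, pr)
  cle <- simulate_cle(net, p0, pr, seed = 123)
  expect_lt(max(abs(unclass(cle) - unclass(ode))), 1e-6)
})

test_that("total phosphatase is conserved along ODE and CLE paths", {
  pr <- stress_protocol(t_end = 30)
  for (tr in list(simulate_ode(net, params, pr),
                  simulate_cle(net, params, pr, seed = 4))) {
    post <- tr[, "time_h"] >= 0
    tot <- tr[post, "P"] + tr[post, "PVP"]
    expect_lt(diff(range(tot)), 1e-9)
    expect_equal(tot[1], params$p_stress, tolerance = 1e-9)
  }
  # modified model conserves P + PI + PVP
  netm <- modified_network(params)
  trm <- simulate_cle(netm, params, pr, seed = 4)
  post <- trm[, "time_h"] >= 0
  totm <- trm[post, "P"] + trm[post, "PI"] + trm[post, "PVP"]
  expect_lt(diff(range(totm)), 1e-9)
})

test_that("identical seeds give bit-identical stochastic paths", {
  pr <- stress_protocol(t_end = 5)
  st <- sim_settings(dt = 0.002)
  a <- simulate_cle(net, params, pr, st, seed = 42)
  b <- simulate_cle(net, params, pr, st, seed = 42)
  expect_identical(unclass(a), unclass(b))
  c <- simulate_cle(net, params, pr, st, seed = 43)
  expect_false(identical(unclass(a), unclass(c)))
  pssa <- sb_params(p_init = 0, p_stress = 10)
  s1 <- simulate_ssa(net, pssa, pr, seed = 7)
  s2 <- simulate_ssa(net, pssa, pr, seed = 7)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("the deterministic path converges at first order in dt", {
  pr <- stress_protocol(t_end = 30)
  t1 <- simulate_ode(net, params, pr, sim_settings(dt = 0.002))
  t2 <- simulate_ode(net, params, pr, sim_settings(dt = 0.001))
  t3 <- simulate_ode(net, params, pr, sim_settings(dt = 0.0005))
  d1 <- max(abs(unclass(t1) - unclass(t2)))
  d2 <- max(abs(unclass(t2) - unclass(t3)))
  # halving dt halves the path difference (order-one scheme); the sup norm
  # is dominated by the fast phosphatase-binding layer at stress onset
  expect_lt(d2, d1)
  expect_gt(d1 / d2, 1.6)
  expect_lt(d1 / d2, 2.6)
  expect_lt(max(abs(t2[, "sigB"] - t3[, "sigB"])), 0.01)
})

test_that("trajectory grid covers burn-in to end with stress on the grid", {
  pr <- stress_protocol(-10, 0, 20)
  tr <- simulate_ode(net, params, pr, sim_settings(dt = 0.002))
  t <- tr[, "time_h"]
  expect_true(all(diff(t) > 0))
  expect_equal(min(t), -10)
  expect_equal(max(t), 20)
  expect_true(any(abs(t - 0) < 1e-12))
  # the sample at the stress time reflects the post-stress state
  expect_equal(tr[which.min(abs(t)), "P"],
               tr[max(which(t < 0)), "P"] + params$p_stress - params$p_init,
               tolerance = 1e-9)
})

test_that("Langevin species may dip negative but the path stays finite", {
  p <- sb_params(kK2 = 9, eta = 0.06, p_stress = 0.3)
  tr <- simulate_cle(net, p, stress_protocol(t_end = 40),
                     sim_settings(dt = 5e-4), seed = 2)
  expect_true(all(is.finite(tr)))
  expect_lt(min(tr[, -1]), 0)  # transient negative excursions tolerated
})

test_that("ensembles are seeded deterministically and averaged pointwise", {
  pr <- stress_protocol(t_end = 5)
  st <- sim_settings(dt = 0.002)
  e <- simulate_ensemble(net, params, pr, st, n = 4, base_seed = 10)
  expect_equal(vapply(e, function(tr) attr(tr, "seed"), numeric(1)), 10:13)
  # n = 1 equals a direct call
  e1 <- simulate_ensemble(net, params, pr, st, n = 1, base_seed = 10)
  expect_identical(unclass(e1[[1]]),
                   unclass(simulate_cle(net, params, pr, st, seed = 10)))
  # repeatability
  e2 <- simulate_ensemble(net, params, pr, st, n = 4, base_seed = 10)
  expect_identical(lapply(e, unclass), lapply(e2, unclass))
  # mean lies between the pointwise min and max member, and averages exactly
  em <- ensemble_mean(e)
  ys <- sapply(e, function(tr) tr[, "sigB"])
  expect_true(all(em[, "mean"] <= apply(ys, 1, max) + 1e-12))
  expect_true(all(em[, "mean"] >= apply(ys, 1, min) - 1e-12))
  expect_equal(em[, "mean"], rowMeans(ys))
  # identical trajectories average to themselves
  same <- structure(list(e[[1]], e[[1]]), class = "sb_ensemble")
  expect_equal(ensemble_mean(same)[, "mean"], e[[1]][, "sigB"])
})

test_that("SSA of a birth-death subsystem matches the analytic mean", {
  # constant birth via F = 1/K (the production rate is then flat at v0/K)
  pbd <- sb_params(v0 = 2, F = 5, K = 0.2, kdeg = 0.7, p_init = 0,
                   p_stress = 1)
  netbd <- core_network(pbd)
  spec <- sigbpulse:::compile_spec(netbd, pbd)
  spec$rate[] <- 0
  spec$rate[1] <- 1
  spec$rate[which(netbd$rxn$description == "degradation sigB")] <- 0.7
  b <- 2 / 0.2
  set.seed(99)
  vals <- vapply(1:300, function(i)
    sigbpulse:::ssa_simulate_cpp(spec, numeric(10), 0, 100, 30, c(0, 30),
                                 numeric(10))[2, 1], numeric(1))
  expect_lt(abs(mean(vals) - b / 0.7), 3 * stats::sd(vals) / sqrt(300))
})

test_that("SSA counts stay non-negative integers and conserve phosphatase", {
  p <- sb_params(p_init = 0, p_stress = 20, kK2 = 7)
  tr <- simulate_ssa(net, p, stress_protocol(t_end = 40), seed = 3)
  x <- tr[, -1]
  expect_true(all(x == round(x)))
  expect_true(all(x >= 0))
  post <- tr[, "time_h"] >= 0
  expect_true(all(tr[post, "P"] + tr[post, "PVP"] == 20))
  expect_true(all(tr[!post, "P"] + tr[!post, "PVP"] == 0))
})

test_that("SSA ensemble mean matches the ODE for a 50-fold scaled system", {
  # classical system-size scaling: counts = 50 x concentration, bimolecular
  # rates / 50, operon curve rescaled accordingly
  om <- 50
  p <- sb_params()
  pc <- sb_params(kK2 = 7, p_init = 0, p_stress = 1.5)
  psc <- sb_params(kK2 = 7, v0 = p$v0 * om^2, F = p$F / om, K = p$K * om,
                   kBw = p$kBw / om, kB1 = p$kB1 / om, kB2 = p$kB2 / om,
                   kB3 = p$kB3 / om, kB4 = p$kB4 / om, kB5 = p$kB5 / om,
                   kD4 = p$kD4 / om, p_init = 0, p_stress = 1.5 * om)
  prot <- stress_protocol(-5, 0, 10)
  ode <- simulate_ode(core_network(pc), pc, prot)
  acc <- 0
  nrun <- 50
  for (i in seq_len(nrun))
    acc <- acc + simulate_ssa(core_network(psc), psc, prot,
                              seed = i)[, "sigB"] / om
  m <- acc / nrun
  # pointwise agreement once the settling transient has passed; during the
  # steep activation front a minute of event-timing jitter dominates the
  # relative error
  sel <- ode[, "time_h"] >= 1 & ode[, "sigB"] > 1
  expect_lt(max(abs(m[sel] - ode[sel, "sigB"]) / ode[sel, "sigB"]), 0.05)
})

test_that("the mean response peak is non-decreasing in the noise amplitude", {
  pr <- stress_protocol(t_end = 30)
  st <- sim_settings(dt = 5e-4)
  peaks <- vapply(c(0.01, 0.05, 0.1), function(eta) {
    p <- sb_params(eta = eta)
    e <- simulate_ensemble(net, p, pr, st, n = 12, base_seed = 100)
    em <- ensemble_mean(e)
    max(em[em[, "time_h"] >= 0, "mean"])
  }, numeric(1))
  expect_true(all(diff(peaks) > -0.02 * peaks[-length(peaks)]))
})
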