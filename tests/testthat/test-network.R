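params <- sb_params()
net <- core_network(params)
netm <- modified_network(params)

test_that("core network has 10 species and 27 reactions", {
  expect_length(net$species, 10)
  expect_equal(nrow(net$rxn), 27)
  expect_equal(ncol(net$S), 27)
  expect_true(all(net$rxn$noise_group == "core"))
})

test_that("modified network adds 1 species and 3 upstream reactions", {
  expect_length(netm$species, 11)
  expect_equal(nrow(netm$rxn), 30)
  expect_equal(sum(netm$rxn$noise_group == "upstream"), 3)
  expect_true("PI" %in% netm$species)
})

test_that("dimerisation has net change (W: -2, W2: +1) and combinatorial propensity", {
  j <- which(net$rxn$type == "dimer")
  expect_equal(unname(net$S["W", j]), -2L)
  expect_equal(unname(net$S["W2", j]), 1L)
  st <- init_state(net, params)
  st[["W"]] <- 2
  a <- propensities(net, st, sb_params(kBw = 3600))
  expect_equal(a[j], 3600 * 2^2 / 2)  # 7200
  # molecule-count combinatorics
  ad <- propensities(net, st, sb_params(kBw = 3600), discrete = TRUE)
  expect_equal(ad[j], 3600 * 2 * 1 / 2)
})

test_that("all-zero state leaves only the three production propensities nonzero", {
  st <- stats::setNames(numeric(10), net$species)
  a <- propensities(net, st, params)
  nonzero <- which(a != 0)
  expect_equal(sort(nonzero), 1:3)
  f0 <- sigbpulse:::production_rate(0, params, net$production_form)
  expect_equal(a[1:3], f0 * c(1, params$lambda_W, params$lambda_V))
  # under the offset parse, the basal rate equals v0 exactly
  net_off <- core_network(params, production_form = "offset")
  a_off <- propensities(net_off, st, params)
  expect_equal(a_off[1], params$v0)
  expect_equal(a_off[2], params$lambda_W * params$v0)
})

test_that("unimolecular dissociation is mass action on the complex", {
  st <- stats::setNames(numeric(10), net$species)
  st[["W2V"]] <- 1
  a <- propensities(net, st, sb_params(kD1 = 18))
  j <- which(net$rxn$description == "dissociation W2V -> W2 + V")
  expect_equal(a[j], 18)
})

test_that("propensities are linear in the rate constants", {
  set.seed(11)
  st <- stats::setNames(abs(rnorm(10)), net$species)
  mass <- c("kBw", "kDw", "kB1", "kB2", "kB3", "kB4", "kB5",
            "kD1", "kD2", "kD3", "kD4", "kD5", "kK1", "kK2", "kP", "kdeg")
  p2 <- params
  for (nm in mass) p2[[nm]] <- 2 * p2[[nm]]
  a1 <- propensities(net, st, params)
  a2 <- propensities(net, st, p2)
  prod_rows <- net$rxn$type == "production"
  expect_equal(a2[!prod_rows], 2 * a1[!prod_rows])
  expect_equal(a2[prod_rows], a1[prod_rows])
  # production scales linearly in the base rate v0
  p3 <- params; p3$v0 <- 2 * p3$v0
  a3 <- propensities(net, st, p3)
  expect_equal(a3[prod_rows], 2 * a1[prod_rows])
})

test_that("total phosphatase is conserved by every reaction (columnwise)", {
  expect_true(all(colSums(net$S[c("P", "PVP"), ]) == 0))
  expect_true(all(colSums(netm$S[c("P", "PI", "PVP"), ]) == 0))
  # and total (P + PI + PVP) column sums are zero reaction by reaction for
  # all 30 modified reactions
  expect_equal(unname(colSums(netm$S[c("P", "PI", "PVP"), ])), rep(0, 30))
})

test_that("eta_freq = 0 reduces the modified drift to the core drift", {
  p <- sb_params(eta_freq = 0)
  set.seed(3)
  st <- stats::setNames(abs(rnorm(11)), netm$species)
  d_mod <- drift(netm, st, p)
  names(d_mod) <- netm$species
  d_core <- drift(net, st[net$species], p)
  names(d_core) <- net$species
  expect_equal(d_mod[net$species], d_core, tolerance = 1e-12)
  # the three switching propensities vanish identically
  a <- propensities(netm, st, p)
  expect_equal(a[netm$rxn$noise_group == "upstream"], rep(0, 3))
})

test_that("drift Jacobian matches central finite differences", {
  for (network in list(net, netm)) {
    set.seed(7)
    x <- stats::setNames(abs(rnorm(length(network$species))), network$species)
    J <- drift_jacobian(network, x, params)
    h <- 1e-6
    Jn <- sapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (drift(network, xp, params) - drift(network, xm, params)) / (2 * h)
    })
    expect_lt(max(abs(J - Jn)), 1e-5)
  }
})

test_that("R and compiled drift/propensities agree at random states", {
  spec <- sigbpulse:::compile_spec(net, params)
  set.seed(5)
  for (k in 1:20) {
    x <- abs(rnorm(10))
    names(x) <- net$species
    expect_lt(max(abs(drift(net, x, params) -
                      as.numeric(sigbpulse:::drift_cpp(spec, x)))), 1e-9)
    expect_equal(propensities(net, x, params),
                 as.numeric(sigbpulse:::propensities_cpp(spec, x, FALSE)),
                 tolerance = 1e-12)
  }
})

test_that("stress step raises free phosphatase by p_stress - p_init", {
  p <- sb_params(p_init = 0.001, p_stress = 0.4)
  st <- init_state(net, p)
  expect_equal(st[["P"]], 0.001)
  st2 <- apply_stress(st, net, p)
  expect_equal(st2[["P"]], 0.4)
  expect_equal(st2[setdiff(names(st2), "P")], st[setdiff(names(st), "P")])
  # modified model: both pools rise
  stm <- apply_stress(init_state(netm, p), netm, p)
  expect_equal(stm[["P"]], 0.4)
  expect_equal(stm[["PI"]], 0.4)
  # degenerate stress leaves the state unchanged
  pd <- sb_params(p_init = 0.2, p_stress = 0.2)
  expect_equal(apply_stress(init_state(net, pd), net, pd),
               init_state(net, pd))
})

test_that("strict propensity mode rejects negative amounts", {
  st <- init_state(net, params)
  st[["V"]] <- -0.1
  expect_error(propensities(net, st, params, strict = TRUE), "V")
  expect_silent(propensities(net, st, params, strict = FALSE))
})
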