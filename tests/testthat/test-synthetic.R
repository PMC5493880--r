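test_that("chain generator meets its documented contract", {
  m <- make_chain_model(3, 10)
  expect_equal(solve_fba(m)$objective_value, 10, tolerance = 1e-9)
  expect_equal(nrow(make_chain_model(1, 5)$reactions), 3)
  expect_equal(simulate_deletion(m, genes = "gene_2")$status, "infeasible")
})

test_that("branched generator meets its documented contract", {
  m <- make_branched_model()
  expect_equal(solve_fba(m)$objective_value,
               attr(m, "documented_optimum"), tolerance = 1e-9)
  fva <- solve_fva(m, objective_fraction = 1, reaction_ids = c("P1", "P2"))
  expect_equal(fva$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fva$max, c(10, 10), tolerance = 1e-6)
})

test_that("mini-core structure is pinned", {
  m <- minicore_cached()
  expect_equal(length(m$genes), 56)
  expect_equal(nrow(m$metabolites), 74)
  expect_equal(nrow(m$reactions), 82)
  # digest pins the fixture: a silent change to the network is an error
  expect_identical(model_digest(m), MINICORE_DIGEST)
})

test_that("mini-core grows on glucose, acetate, lactate; not on xylose", {
  m <- minicore_cached()
  run <- function(cs, u, adds = NULL) {
    run_growth_scenario(m, scenario_config(carbon_source = cs,
                                           uptake_rate = u,
                                           additions = adds))
  }
  expect_gt(run("EX_glc__D_e", 4)$growth_rate, 0.1)
  expect_gt(run("EX_ac_e", 8)$growth_rate, 0.05)
  expect_gt(run("EX_lac__L_e", 6)$growth_rate, 0.05)
  expect_equal(run("EX_xyl__D_e", 4)$growth_rate, 0)
  expect_gt(run("EX_xyl__D_e", 4, "xylose_ecoli")$growth_rate, 0.1)
  expect_equal(run("EX_glyc_e", 6)$growth_rate, 0)
  expect_gt(run("EX_glyc_e", 6, "glycerol_ecoli")$growth_rate, 0.1)
})

test_that("pgi deletion reroutes glucose through the oxidative PPP", {
  m <- minicore_cached()
  d <- simulate_deletion(m, genes = "pgi")
  expect_equal(d$status, "optimal")
  g6p_drain <- -m$stoichiometry$BIOMASS[["g6p_c"]] * d$objective_value
  # tolerance reflects the 1e-6 relative objective cut in the
  # total-flux-minimal solution
  expect_equal(d$fluxes[["G6PDH2r"]], 4 - g6p_drain, tolerance = 1e-5)
})

test_that("13C-style constraint tables honor their construction", {
  m <- minicore_cached()
  wt <- wt_state_cached()
  # width 0: every interval is the true flux plus/minus the 0.5 floor
  cs0 <- make_c13_constraints(m, wt, width_fraction = 0)
  v <- wt$fluxes[cs0$reaction_id]
  expect_equal(cs0$lb, as.numeric(v) - 0.5, tolerance = 1e-12)
  expect_equal(cs0$ub, as.numeric(v) + 0.5, tolerance = 1e-12)
  # true flux always inside, at any width
  for (w in c(0.05, 0.2)) {
    cs <- make_c13_constraints(m, wt, width_fraction = w, seed = 99)
    v <- wt$fluxes[cs$reaction_id]
    expect_true(all(cs$lb <= v + 1e-12 & v <= cs$ub + 1e-12))
  }
  # deterministic per seed, different across seeds
  a <- make_c13_constraints(m, wt, width_fraction = 0.1, seed = 1)
  b <- make_c13_constraints(m, wt, width_fraction = 0.1, seed = 1)
  c3 <- make_c13_constraints(m, wt, width_fraction = 0.1, seed = 2)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$lb, c3$lb)))
  # generation must not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_c13_constraints(m, wt, seed = 5))
  expect_identical(runif(1), before)
})

test_that("the wild-type reference state is feasible and carries pck flux", {
  m <- minicore_cached()
  wt <- wt_state_cached()
  expect_equal(wt$status, "optimal")
  S <- build_stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% wt$fluxes)), 1e-6)
  expect_equal(wt$fluxes[["PPCK"]], 0.3, tolerance = 1e-9)
  expect_gt(wt$fluxes[["PC"]], 0.3)  # anaplerosis exceeds the cycling
})
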