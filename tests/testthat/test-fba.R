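test_that("FBA solves the chain toy exactly", {
  m <- make_chain_model(3, 10)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # uptake is an equality: closing the only path makes the LP infeasible
  closed <- knockout_reactions(m, "CONV2")
  expect_equal(solve_fba(closed)$status, "infeasible")
  # bound-only uptake instead gives a zero optimum
  relaxed <- set_bounds(closed, "EX_x0_e", ub = 0)
  sol0 <- solve_fba(relaxed)
  expect_equal(sol0$status, "optimal")
  expect_equal(sol0$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA optimum matches the independent dense-LP oracle on toys", {
  set.seed(11)
  toys <- list(make_chain_model(1, 10), make_chain_model(4, 3.5),
               make_branched_model(), minicore_cached())
  small <- c(TRUE, TRUE, TRUE, FALSE)
  for (k in seq_along(toys)) {
    if (!small[k]) next  # oracle is for dense toy problems
    m <- toys[[k]]
    sol <- solve_fba(m)
    ora <- oracle_optimum(m, m$objective, "max")
    expect_equal(sol$objective_value, ora$value, tolerance = 1e-6)
    # random bound perturbations keep the two solvers in agreement
    for (rep in 1:5) {
      m2 <- m
      j <- sample(nrow(m2$reactions), 1)
      if (m2$reactions$lb[j] <= 0 && m2$reactions$ub[j] > 1) {
        m2$reactions$ub[j] <- runif(1, 1, 8)
      }
      s2 <- solve_fba(m2)
      o2 <- oracle_optimum(m2, m2$objective, "max")
      if (s2$status == "optimal" && o2$status == "optimal") {
        expect_equal(s2$objective_value, o2$value, tolerance = 1e-6)
      } else {
        expect_identical(s2$status == "optimal", o2$status == "optimal")
      }
    }
  }
})

test_that("steady state holds at every reported optimum", {
  for (m in list(make_chain_model(3, 10), make_branched_model(),
                 minicore_cached())) {
    S <- build_stoichiometric_matrix(m)
    for (sol in list(solve_fba(m), minimize_total_flux_at_optimum(m))) {
      expect_equal(sol$status, "optimal")
      expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
      expect_true(all(sol$fluxes >= m$reactions$lb - 1e-6))
      expect_true(all(sol$fluxes <= m$reactions$ub + 1e-6))
    }
  }
})

test_that("biomass optimum scales linearly with all uptake bounds", {
  # homogeneity requires no constant demands: zero the maintenance floor
  m <- set_bounds(minicore_cached(), "ATPM", lb = 0)
  base <- solve_fba(m)$objective_value
  for (c_scale in c(0.5, 2)) {
    m2 <- m
    ex <- m2$reactions$is_exchange
    m2$reactions$lb[ex] <- m2$reactions$lb[ex] * c_scale
    m2$reactions$ub[ex] <- m2$reactions$ub[ex] * c_scale
    expect_equal(solve_fba(m2)$objective_value, base * c_scale,
                 tolerance = 1e-6)
  }
})

test_that("total-flux minimization zeroes futile cycles, keeps optimum", {
  # chain plus an explicit 2-reaction futile cycle
  m <- make_chain_model(2, 10)
  m <- augment_model(m, list(
    reaction("CYC_F", c(x1_e = -1, x2_e = 1), lb = 0),
    reaction("CYC_R", c(x2_e = -1, x1_e = 1), lb = 0)
  ))
  p <- minimize_total_flux_at_optimum(m)
  expect_equal(p$objective_value, 10, tolerance = 1e-5)
  # no net gain from the cycle pair: parsimony forces one of them to zero
  expect_lt(min(p$fluxes[["CYC_F"]], p$fluxes[["CYC_R"]]), 1e-6)
  # two identical parallel paths: total flux equals the single-path total
  br <- make_branched_model()
  pb <- minimize_total_flux_at_optimum(br)
  expect_equal(pb$fluxes[["P1"]] + pb$fluxes[["P2"]], 10,
               tolerance = 1e-6)
})

test_that("FVA matches brute-force per-reaction LPs and nests by fraction", {
  br <- make_branched_model()
  opt <- solve_fba(br)$objective_value
  fva1 <- solve_fva(br, objective_fraction = 1.0)
  # oracle: per-reaction min/max with an objective floor
  for (rid in c("P1", "P2", "EX_b_e", "REOX")) {
    lo <- oracle_optimum(br, rid, "min", floor_reaction = "EX_b_e",
                         floor_value = opt - 1e-9)
    hi <- oracle_optimum(br, rid, "max", floor_reaction = "EX_b_e",
                         floor_value = opt - 1e-9)
    row <- fva1[fva1$reaction_id == rid, ]
    expect_equal(row$min, lo$value, tolerance = 1e-6)
    expect_equal(row$max, hi$value, tolerance = 1e-6)
  }
  # the two parallel routes are individually free over (0, 10)
  expect_equal(fva1$min[fva1$reaction_id == "P1"], 0, tolerance = 1e-6)
  expect_equal(fva1$max[fva1$reaction_id == "P1"], 10, tolerance = 1e-6)
  # chain at fraction 1: unique path pins every reaction at 10
  ch <- make_chain_model(3, 10)
  fch <- solve_fva(ch, objective_fraction = 1.0,
                   reaction_ids = c("CONV1", "CONV2", "CONV3"))
  expect_true(all(abs(fch$min - 10) < 1e-6))
  expect_true(all(abs(fch$max - 10) < 1e-6))
  # fraction-0 ranges contain fraction-1 ranges; FBA flux lies inside
  fva0 <- solve_fva(br, objective_fraction = 0)
  sol <- solve_fba(br)
  for (i in seq_len(nrow(fva1))) {
    expect_lte(fva0$min[i], fva1$min[i] + 1e-9)
    expect_gte(fva0$max[i], fva1$max[i] - 1e-9)
    v <- sol$fluxes[[fva1$reaction_id[i]]]
    expect_gte(v, fva1$min[i] - 1e-6)
    expect_lte(v, fva1$max[i] + 1e-6)
  }
})

test_that("deletion simulation routes through GPRs", {
  ch <- make_chain_model(2, 10)
  expect_equal(simulate_deletion(ch, genes = "gene_1")$status,
               "infeasible")
  suppressWarnings({
    same <- simulate_deletion(ch, genes = "unrelated_gene")
  })
  ref <- minimize_total_flux_at_optimum(ch)
  expect_equal(same$fluxes, ref$fluxes, tolerance = 1e-9)
})

test_that("cofactor accounting balances production and consumption", {
  br <- make_branched_model()
  p <- minimize_total_flux_at_optimum(br)
  acc <- cofactor_production(br, p, "nadh_c")
  expect_equal(acc$total, attr(br, "documented_cofactor_demand"),
               tolerance = 1e-6)
  expect_equal(sum(acc$production) - sum(acc$consumption), 0,
               tolerance = 1e-6)
  expect_error(cofactor_production(br, p, "nope_c"), "unknown metabolite")
  # single producer at known flux
  expect_equal(acc$consumption[["REOX"]], 10, tolerance = 1e-6)
})

test_that("theoretical maximum anchors production floors", {
  ch <- make_chain_model(3, 10)
  expect_equal(theoretical_maximum(ch, "EX_x3_e"), 10, tolerance = 1e-6)
  ch0 <- set_bounds(ch, "CONV1", lb = 0, ub = 0)
  expect_error(theoretical_maximum(ch0, "EX_x3_e"), "infeasible")
  chb <- set_bounds(ch, "EX_x0_e", lb = -10, ub = 0)
  chb <- set_bounds(chb, "CONV1", lb = 0, ub = 0)
  expect_equal(theoretical_maximum(chb, "EX_x3_e"), 0, tolerance = 1e-9)
})
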