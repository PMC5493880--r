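test_that("stoichiometric matrix lays out coefficients correctly", {
  m <- make_chain_model(2, 10)
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  expect_equal(S["x0_e", "CONV1"], -1)
  expect_equal(S["x1_e", "CONV1"], 1)
  expect_equal(S["x0_e", "EX_x0_e"], -1)
  # mass-weighted column sums vanish for balanced internal reactions
  mc <- minicore_cached()
  Smc <- build_stoichiometric_matrix(mc)
  mw <- vapply(mc$metabolites$formula, molecular_weight, numeric(1))
  bal <- check_mass_charge_balance(mc)
  for (rid in bal$reaction_id[bal$status == "balanced"]) {
    expect_lt(abs(sum(Smc[, rid] * mw)), 1e-6)
  }
})

test_that("model invariants are enforced", {
  mets <- rbind(metabolite("a_e", formula = "C"),
                metabolite("b_c", formula = "C"))
  expect_error(metabolic_model(mets, list(
    reaction("R1", c(a_e = -1, zz_c = 1))
  )), "undeclared metabolite")
  expect_error(metabolic_model(mets, list(
    reaction("EX_b", c(b_c = -1))
  )), "non-extracellular")
  expect_error(reaction("R", c(a_e = -1), lb = 2, ub = 1), "lower bound")
  expect_error(metabolic_model(mets, list(
    reaction("R1", c(a_e = -1, b_c = 1)),
    reaction("R1", c(a_e = -1, b_c = 1))
  )), "duplicate reaction")
})

test_that("gene deletions disable exactly the GPR-inactive reactions", {
  m <- make_chain_model(3, 10)
  del <- apply_gene_deletions(m, "gene_2")
  expect_identical(del$disabled, "CONV2")
  i <- match("CONV2", del$model$reactions$id)
  expect_equal(del$model$reactions$lb[i], 0)
  expect_equal(del$model$reactions$ub[i], 0)
  # OR rule survives single deletion
  m2 <- metabolic_model(
    rbind(metabolite("a_e", formula = "C"), metabolite("b_e", formula = "C")),
    list(reaction("EX_a", c(a_e = -1), lb = -10, ub = -10),
         reaction("R1", c(a_e = -1, b_e = 1), lb = 0, gpr = "g1 or g2"),
         reaction("EX_b", c(b_e = -1), lb = 0)),
    objective = "EX_b")
  del2 <- apply_gene_deletions(m2, "g1")
  expect_length(del2$disabled, 0)
  # unknown gene: warning, not error, and a no-op
  expect_warning(del3 <- apply_gene_deletions(m, "not_a_gene"),
                 "not in model")
  expect_identical(del3$model$reactions, m$reactions)
})

test_that("gene deletion is idempotent", {
  m <- minicore_cached()
  once <- apply_gene_deletions(m, c("pgi", "ldh"))$model
  twice <- apply_gene_deletions(once, c("pgi", "ldh"))$model
  expect_identical(once$reactions, twice$reactions)
})

test_that("model augmentation validates and errors on duplicates", {
  m <- make_chain_model(1, 5)
  add <- reaction("BYPASS", c(x0_e = -1, x1_e = 1), lb = 0)
  m2 <- augment_model(m, list(add))
  expect_true("BYPASS" %in% m2$reactions$id)
  expect_error(augment_model(m2, list(add)), "already present")
  expect_error(
    augment_model(m, list(reaction("R9", c(x0_e = -1, nope_c = 1)))),
    "undeclared metabolite")
})
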