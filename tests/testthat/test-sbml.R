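test_that("SBML subset round-trips field-by-field", {
  for (m in list(make_chain_model(2, 10), minicore_cached())) {
    path <- tempfile(fileext = ".xml")
    write_sbml_subset(m, path)
    m2 <- read_sbml_subset(path)
    expect_identical(m$metabolites, m2$metabolites)
    expect_identical(m$reactions$id, m2$reactions$id)
    expect_equal(m$reactions$lb, m2$reactions$lb)
    expect_equal(m$reactions$ub, m2$reactions$ub)
    expect_identical(m$reactions$gpr, m2$reactions$gpr)
    expect_equal(m$stoichiometry, m2$stoichiometry)
    expect_identical(sort(m$genes), sort(m2$genes))
    expect_identical(m$objective, m2$objective)
    unlink(path)
  }
})

test_that("reversible bounds of (-1000, 1000) survive the round-trip", {
  m <- minicore_cached()
  path <- tempfile(fileext = ".xml")
  write_sbml_subset(m, path)
  m2 <- read_sbml_subset(path)
  i <- match("PGI", m2$reactions$id)
  expect_equal(m2$reactions$lb[i], -1000)
  expect_equal(m2$reactions$ub[i], 1000)
  unlink(path)
})

test_that("documents with constructs outside the subset are rejected", {
  m <- make_chain_model(1, 5)
  path <- tempfile(fileext = ".xml")
  write_sbml_subset(m, path)
  doc <- xml2::read_xml(path)
  mdl <- xml2::xml_find_first(
    doc, "//s:model", c(s = "http://www.sbml.org/sbml/level3/version1/core"))
  xml2::xml_add_child(mdl, "listOfEvents")
  xml2::write_xml(doc, path)
  expect_error(read_sbml_subset(path), "listOfEvents")
  unlink(path)
})

test_that("an independent SBML implementation reads the written model", {
  # cobrapy (python) as external validator and FBA cross-check
  m <- minicore_cached()
  path <- tempfile(fileext = ".xml")
  write_sbml_subset(m, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    sprintf("mod = cobra.io.read_sbml_model('%s')", path),
    "sol = mod.optimize()",
    "print(len(mod.genes), len(mod.metabolites), len(mod.reactions),",
    "      sol.status, round(sol.objective_value, 6))"
  ), script)
  out <- tryCatch(
    system2("python", script, stdout = TRUE, stderr = FALSE),
    warning = function(w) character(0), error = function(e) character(0))
  expect_true(length(out) >= 1)
  parts <- strsplit(tail(out, 1), " +")[[1]]
  expect_equal(as.integer(parts[1]), length(m$genes))
  expect_equal(as.integer(parts[2]), nrow(m$metabolites))
  expect_equal(as.integer(parts[3]), nrow(m$reactions))
  expect_equal(parts[4], "optimal")
  ours <- solve_fba(m)$objective_value
  expect_equal(as.numeric(parts[5]), ours, tolerance = 1e-4)
  unlink(c(path, script))
})
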