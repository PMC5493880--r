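test_that("robustness scan base case reports relative fluxes of one", {
  m <- minicore_cached()
  scan <- robustness_scan(m, "CS", c(1.0, 1.2),
                          reporter_ids = c("ICDHyr", "GND"))
  expect_equal(scan$status[1], "optimal")
  # agreement up to the optimality-cut relaxation of the parsimonious step
  expect_equal(scan$ICDHyr[1], 1, tolerance = 1e-4)
  expect_equal(scan$GND[1], 1, tolerance = 1e-4)
})

test_that("zero reference flux is rejected", {
  m <- minicore_cached()
  expect_error(robustness_scan(m, "LDH_L", c(1, 2), "CS"),
               "zero")
})

test_that("infeasible multipliers are recorded and the scan continues", {
  ch <- make_chain_model(2, 10)
  # pinned conversion flux beyond the fixed uptake is infeasible
  scan <- robustness_scan(ch, "CONV1", c(1.0, 2.0, 0.5),
                          reporter_ids = "CONV2")
  expect_equal(scan$status, c("optimal", "infeasible", "infeasible"))
  expect_equal(scan$multiplier, c(1.0, 2.0, 0.5))
})

test_that("aconitase scan on the proline producer is unimodal", {
  # emulates the acn upregulation study: pin the aconitase flux at
  # multiples of its wild-type value, maximize proline export with a
  # biomass floor, and follow the reporters
  m <- minicore_cached()
  dp <- apply_gene_deletions(m, "putA")$model
  dp <- set_bounds(dp, "BIOMASS", lb = 0.3)
  wt <- wt_state_cached()
  ks <- seq(1, 5, by = 0.5)
  scan <- robustness_scan(dp, "ACONT", ks,
                          reporter_ids = c("CS", "ICDHyr", "VALTA",
                                           "EX_pro__L_e"),
                          objective = "EX_pro__L_e", reference = wt)
  ok <- scan$status == "optimal"
  expect_gt(sum(ok), 3)
  pro <- scan$EX_pro__L_e_flux[ok]
  # unimodal: increases to an interior maximum, then decreases
  peak <- which.max(pro)
  expect_gt(peak, 1)
  expect_lt(peak, length(pro))
  expect_true(all(diff(pro[seq_len(peak)]) > -1e-9))
  expect_true(all(diff(pro[peak:length(pro)]) < 1e-9))
  # citrate synthase and isocitrate dehydrogenase scale up with aconitase
  expect_true(all(diff(scan$CS[ok]) > -1e-9))
  # valine drain stays below its wild-type level throughout
  expect_true(all(scan$VALTA[ok] < 1))
  # infeasible high multipliers are recorded, not fatal
  expect_true(all(scan$status %in% c("optimal", "infeasible")))
})
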