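# Independent oracle used below: under the half-saturation reduction the
# four T-cell steady-state equations are linear in the signalling maxima;
# solve them directly from first principles, separately from the package's
# calibration path.
# The unknown vector is (sigma_12, sigma_4, sigma_21, sigma_beta); each
# T-cell equation contributes one row. Every saturation factor is 1/2
# (half-saturation = steady state), the IFN-gamma and IL-4 resistances of
# Th17 each halve the signal, TNF-alpha halves the Treg signal, and the
# sigma_6 = sigma_21, sigma_10 = sigma_beta ties double their rows.
oracle_sigmas <- function(st = healthy_state(), kin = params_pr$kin,
                          sat = params_pr$sat) {
  M <- st[["M1"]] + st[["M2"]]
  h <- function(x, c) 1 / (1 + x / c)
  A <- matrix(0, 4, 4)
  A[1, 1] <- (1/2) * (1/2) * M * h(st[["T2"]], sat$gamma_2) * h(st[["Tr"]], sat$gamma_r1)
  A[2, 2] <- (1/2) * M * h(st[["T1"]], sat$gamma_1) * h(st[["Tr"]], sat$gamma_r2)
  A[3, 3] <- (1/2 + 1/2) * (1/2) * M / (2 * 2) * h(st[["Tr"]], sat$gamma_r17)
  A[4, 4] <- (1/2 + 1/2) * (1/2) * M / 2 * h(st[["T17"]], sat$gamma_17)
  b <- c(kin$mu_1 * st[["T1"]] -
           kin$sigma_2 * (1/2) * st[["T1"]] *
           h(st[["T2"]], sat$gamma_2) * h(st[["Tr"]], sat$gamma_r1),
         kin$mu_2 * st[["T2"]], kin$mu_17 * st[["T17"]],
         kin$mu_r * st[["Tr"]])
  stats::setNames(solve(A, b),
                  c("sigma_12", "sigma_4", "sigma_21", "sigma_beta"))
}

test_that("rate_from_balance reproduces the published IL-4 derivation", {
  expect_equal(rate_from_balance(3e-2, 15e-9, 349.37), 1.74685e-4,
               tolerance = 1e-6)
  expect_identical(rate_from_balance(0.1, 0, 10), 0)
  # IL-21 production implied by the published steady state
  nu <- rate_from_balance(3.37e-1, 4.25e-6, 63.98)
  expect_lt(abs(nu - 8.05e-4) / 8.05e-4, 0.003)
  expect_error(rate_from_balance(0, 1e-9, 10), "cell density")
})

test_that("cytokine anchoring is proportional and scale-homogeneous", {
  ref <- healthy_reference(c(IL6 = 4, IL10 = 1, TNFa = 2, Tbet = 1,
                             GATA3 = 1, RORgt = 1, Foxp3 = 1))
  anc <- anchor_cytokines(ref, il6_anchor = 8e-6)
  expect_equal(anc$lambda_c, 2e-6)
  expect_equal(unname(anc$concentrations["Ialpha"]), 4e-6)
  # rescaling all mRNA means leaves concentrations unchanged
  ref2 <- healthy_reference(c(IL6 = 40, IL10 = 10, TNFa = 20, Tbet = 10,
                              GATA3 = 10, RORgt = 10, Foxp3 = 10))
  anc2 <- anchor_cytokines(ref2, il6_anchor = 8e-6)
  expect_equal(anc2$concentrations, anc$concentrations)
  expect_equal(anc2$lambda_c, anc$lambda_c / 10)
  # concentrations scale only with the anchor
  anc3 <- anchor_cytokines(ref, il6_anchor = 1.6e-5)
  expect_equal(anc3$concentrations, 2 * anc$concentrations)
  # the default baselines anchor to the published concentrations
  anc4 <- anchor_cytokines(healthy_reference(baseline_mrna_means()))
  expect_equal(unname(anc4$concentrations),
               unname(hs[c("I6", "Ialpha", "I10")]))
})

test_that("calibration recovers the published signalling maxima", {
  cal <- calibrate_healthy()
  printed <- c(sigma_12 = 10.93, sigma_4 = 1.94, sigma_21 = 156.17,
               sigma_6 = 156.17, sigma_beta = 14.02, sigma_10 = 14.02)
  for (nm in names(printed))
    expect_lt(abs(cal$estimates[[nm]] - printed[[nm]]) / printed[[nm]], 0.005)
  # ties
  expect_identical(cal$estimates[["sigma_6"]], cal$estimates[["sigma_21"]])
  expect_identical(cal$estimates[["sigma_10"]], cal$estimates[["sigma_beta"]])
  # agreement with the hand-coded linear-reduction oracle
  orc <- oracle_sigmas()
  expect_equal(unname(cal$estimates[names(orc)]), unname(orc),
               tolerance = 1e-12)
})

test_that("calibration from an mRNA reference pins lambda_T via IL-10", {
  ref <- healthy_reference(baseline_mrna_means())
  cal <- calibrate_healthy(healthy_ref = ref)
  expect_equal(cal$estimates[["lambda_c"]], 1e-8)
  # lambda_T is pinned by the IL-10 balance; the published Treg density
  # satisfies that balance to ~0.2%, so lambda_T lands within 1% of 1e-4
  expect_lt(abs(cal$estimates[["lambda_T"]] - 1e-4) / 1e-4, 0.01)
  expect_equal(unname(cal$steady_state[c("T1", "T2", "T17", "Tr")]),
               unname(hs[c("T1", "T2", "T17", "Tr")]), tolerance = 0.01)
  expect_lt(max(abs(cal$residuals)), 1e-10)
})

test_that("inconsistent master-regulator panels are rejected", {
  bad_ref <- healthy_reference(c(baseline_mrna_means()[-5], GATA3 = 200))
  expect_error(
    calibrate_healthy(healthy_ref = bad_ref,
                      tcell_densities = hs[c("T1", "T2", "T17", "Tr")]),
    "lambda_T")
})

test_that("calibration is dimensionally homogeneous", {
  c0 <- calibrate_healthy()
  scale <- 3.7
  c1 <- calibrate_healthy(
    tcell_densities = scale * hs[c("T1", "T2", "T17", "Tr")],
    anchored = scale * hs[c("I6", "Ialpha", "I10")],
    macrophage_densities = scale * hs[c("M1", "M2")],
    cytokine_targets = scale * hs[c("Igamma", "I2", "I4", "I12", "I21", "Ibeta")])
  # densities and concentrations scaled together: cytokine production rates
  # are per-cell rates and must be invariant; signalling maxima likewise up
  # to the (density-dependent) inhibition factors
  expect_equal(c1$estimates[["nu_6M"]], c0$estimates[["nu_6M"]],
               tolerance = 1e-10)
  expect_equal(c1$estimates[["nu_alpha_1"]], c0$estimates[["nu_alpha_1"]],
               tolerance = 1e-10)
  expect_equal(c1$steady_state, scale * c0$steady_state, tolerance = 1e-10)
})

test_that("self-consistent dialect makes the published state an exact fixed point", {
  expect_equal(params_sc$steady_state, hs, tolerance = 1e-12)
  r <- relative_residuals(params_sc, hs)
  expect_lt(max(abs(r)), 1e-10)
  # integrating 100 weeks from it moves nothing by more than 0.1%
  tr <- integrate_model(params_sc, hs, horizon = 100)
  fin <- unlist(tr[nrow(tr), state_names()])
  expect_lt(max(abs(fin - hs) / hs), 1e-3)
})

test_that("the audit flags the inconsistent printed balances and clears the rest", {
  audit <- audit_printed_parameters()
  flagged <- audit$equation[audit$flagged]
  # these published balances are mutually inconsistent with the published
  # steady state and must be flagged
  expect_true(all(c("Igamma", "I2", "I6", "I12", "M2") %in% flagged))
  res <- stats::setNames(audit$residual, audit$equation)
  # IL-10 and IL-21 balances close to well under 1%
  expect_lt(abs(res[["I10"]]), 0.01)
  expect_lt(abs(res[["I21"]]), 0.005)
  # TNF-alpha closes to ~2%
  expect_lt(abs(res[["Ialpha"]]), 0.05)
  # IFN-gamma is off by more than an order of magnitude
  expect_gt(abs(res[["Igamma"]]), 0.9)
  # T-cell balances hold at printed rounding precision
  expect_lt(max(abs(res[c("T1", "T2", "T17", "Tr")])), 0.005)
})
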