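test_that("saturation and inhibition helpers obey their definitions", {
  expect_identical(saturate(0, 1e-6), 0)
  expect_identical(saturate(1e-6, 1e-6), 0.5)
  # half-saturation at the published TNF-alpha constant
  expect_identical(saturate(9.75e-6, 9.75e-6), 0.5)
  expect_true(saturate(1e3, 1e-6) < 1)
  expect_identical(inhibit(0, 5), 1)
  expect_identical(inhibit(6.06e-2, 6.06e-2), 0.5)
  expect_error(saturate(-1, 1), "concentration")
  expect_error(saturate(1, 0), "half-saturation")
  expect_error(inhibit(-1, 1), "level")
  expect_error(inhibit(1, -1), "constant")
})

test_that("every gating factor is exactly 1/2 at the calibrated equilibrium", {
  s <- params_sc$sat
  for (cyt in c("gamma", "2", "4", "6", "10", "12", "21", "alpha", "beta")) {
    st <- switch(cyt, gamma = "Igamma", alpha = "Ialpha", beta = "Ibeta",
                 paste0("I", cyt))
    expect_equal(saturate(hs[[st]], s[[paste0("zeta_", cyt)]]), 0.5)
  }
  expect_equal(inhibit(hs[["Tr"]], s$gamma_r1), 0.5)
  expect_equal(inhibit(hs[["T17"]], s$gamma_17), 0.5)
})

test_that("all-zero state leaves only basal macrophage activation", {
  d <- model_rhs(rep(0, 15), params_pr)
  expect_equal(unname(d["M1"]), params_pr$kin$f1 * params_pr$kin$M0)
  expect_equal(unname(d["M2"]), params_pr$kin$f2 * params_pr$kin$M0)
  expect_equal(unname(d[setdiff(state_names(), c("M1", "M2"))]),
               rep(0, 13))
})

test_that("IL-21 production-decay balance closes at the published values", {
  st <- hs
  d <- model_rhs(st, params_pr)
  prod <- params_pr$kin$nu_2117 * st[["T17"]]
  expect_lt(abs(d[["I21"]]) / prod, 0.005)
})

test_that("the calibrated steady state is an equilibrium to solver precision", {
  r <- relative_residuals(params_sc, params_sc$steady_state)
  expect_lt(max(abs(r)), 1e-8)
})

test_that("negative states are rejected", {
  bad <- hs; bad["T1"] <- -1e-3
  expect_error(model_rhs(bad, params_sc), "non-negative")
})

test_that("macrophage transitions conserve M1 + M2", {
  # the TGF-beta and IFN-gamma transition terms appear with opposite signs
  # in the two macrophage equations, so d(M1+M2)/dt must not depend on them
  for (st in random_states(5, seed = 42)) {
    d0 <- model_rhs(st, params_sc)
    kin <- params_sc$kin
    kin$sigma_M_beta <- kin$sigma_M_beta * 7.3
    kin$sigma_M_gamma <- kin$sigma_M_gamma * 0.11
    p2 <- ibdimmune:::new_ibd_params(kin, params_sc$sat, "self_consistent")
    d1 <- model_rhs(st, p2)
    expect_equal(d0[["M1"]] + d0[["M2"]], d1[["M1"]] + d1[["M2"]],
                 tolerance = 1e-12)
  }
})

test_that("Jacobian sparsity matches the equation structure", {
  for (st in random_states(3, seed = 7)) {
    st[st == 0] <- hs[st == 0] * 0.3   # interior point for clean differencing
    J <- model_jacobian(st, params_sc)
    nm <- state_names()
    # IL-2 dynamics involve only T1 and IL-2
    expect_equal(unname(which(abs(J["I2", ]) > 1e-8)),
                 unname(match(c("T1", "I2"), nm)))
    # IL-21 dynamics involve only Th17 and IL-21
    expect_equal(unname(which(abs(J["I21", ]) > 1e-8)),
                 unname(match(c("T17", "I21"), nm)))
  }
})

test_that("the printed IL-10 bracket variant is available and differs", {
  p_alt <- default_parameters("printed", eq8_numerator = "Igamma")
  st <- hs; st["Igamma"] <- 5 * st[["Igamma"]]
  d_i2 <- model_rhs(st, params_pr)
  d_ig <- model_rhs(st, p_alt)
  expect_false(isTRUE(all.equal(d_i2[["I10"]], d_ig[["I10"]])))
  # at the healthy state the occupancy I2/(zeta2+I2) is 1/2 by calibration
  expect_equal(model_rhs(hs, params_pr)[["I10"]],
               model_rhs(hs, default_parameters("printed"))[["I10"]])
})

test_that("parameter tables match the published values and round-trip YAML", {
  k <- params_pr$kin
  expect_identical(k$sigma_M_alpha, 2.4)
  expect_identical(k$nu_2117, 8.05e-4)
  expect_identical(k$delta_2, 537.46)
  expect_identical(k$sigma_21, 156.17)
  expect_identical(params_pr$sat$zeta_beta, 6.77e-12)
  expect_identical(params_pr$sat$gamma_2, 5.35e-2)
  expect_identical(unname(hs["T17"]), 3.37e-1)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(params_pr, path)
  p2 <- load_parameters(path)
  expect_equal(p2$kin, params_pr$kin, tolerance = 1e-12)
  expect_equal(p2$sat, params_pr$sat, tolerance = 1e-12)

  # the packaged default config reproduces the printed tables
  cfg <- system.file("extdata", "parameters.yaml", package = "ibdimmune")
  expect_true(nzchar(cfg))
  p3 <- load_parameters(cfg)
  expect_equal(p3$kin, params_pr$kin, tolerance = 1e-12)
})

test_that("dependent rates derive from their fixed ratios", {
  got <- derive_dependent_rates(list(sigma_M_alpha = 2.4, nu_gamma_M = 8.2e-6,
                                     nu_42 = 1.75e-4, nu_10M = 3.72e-4,
                                     sigma_21 = 156.17, sigma_beta = 14.02))
  expect_equal(got$sigma_M10, 24)
  expect_equal(got$sigma_M_beta, 24)
  expect_equal(got$nu_gamma_1, 4.1e-5)
  expect_equal(got$nu_21, 4.1e-5)
  expect_equal(got$nu_4M, 1.75e-4 / 3)
  expect_equal(got$nu_10r, 1.116e-3)
  expect_equal(got$sigma_6, 156.17)
  expect_equal(got$sigma_10, 14.02)
  expect_error(derive_dependent_rates(list(nu_42 = 1)), "sigma_M_alpha")
})
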