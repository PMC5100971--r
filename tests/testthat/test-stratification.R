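ref <- healthy_reference(baseline_mrna_means())

test_that("the Th1/Th2 sign pattern drives classification", {
  expect_identical(classify_patient(1.5 * ref[["Tbet"]], 0.8 * ref[["GATA3"]], ref), 1L)
  expect_identical(classify_patient(0.5 * ref[["Tbet"]], 1.2 * ref[["GATA3"]], ref), 2L)
  expect_identical(classify_patient(1.1 * ref[["Tbet"]], 1.1 * ref[["GATA3"]], ref), 3L)
  expect_identical(classify_patient(0.5 * ref[["Tbet"]], 0.5 * ref[["GATA3"]], ref), 4L)
  expect_error(classify_patient(ref[["Tbet"]], 0.5 * ref[["GATA3"]], ref),
               "unclassifiable")
})

test_that("classification is invariant under common unit rescaling", {
  set.seed(8)
  for (i in 1:20) {
    tb <- ref[["Tbet"]] * runif(1, 0.3, 3)
    ga <- ref[["GATA3"]] * runif(1, 0.3, 3)
    s <- runif(1, 1e-3, 1e3)
    ref2 <- healthy_reference(s * baseline_mrna_means())
    expect_identical(classify_patient(tb, ga, ref),
                     classify_patient(s * tb, s * ga, ref2))
  }
})

test_that("a noise-free default cohort classifies 7/18/17/16", {
  co <- generate_cohort(cohort_spec(noise_cv = 0, seed = 2))
  cls <- classify_cohort(co, ref)
  expect_equal(as.integer(table(cls$assigned_type)), c(7L, 18L, 17L, 16L))
  expect_true(all(cls$assigned_type[co$group == "IBD"] ==
                    co$type[co$group == "IBD"]))
})

test_that("classification round-trips generated types at 10% noise", {
  co <- generate_cohort(cohort_spec(noise_cv = 0.10, seed = 31))
  cls <- classify_cohort(co, cohort_reference(co, from_manifest = TRUE))
  ibd <- co$group == "IBD"
  expect_gte(mean(cls$assigned_type[ibd] == co$type[ibd]), 0.95)
})

test_that("apply_variation multiplies rates and honours ties", {
  p0 <- params_pr
  expect_equal(apply_variation(p0, c(sigma_12 = 0))$kin, p0$kin)
  p2 <- apply_variation(p0, c(sigma_12 = 2.98))
  expect_equal(p2$kin$sigma_12, 43.5014)
  # tie propagation: varying sigma_21 moves sigma_6 identically
  p3 <- apply_variation(p0, c(sigma_21 = 0.49, sigma_beta = -0.5))
  expect_equal(p3$kin$sigma_6, p3$kin$sigma_21)
  expect_equal(p3$kin$sigma_10, p3$kin$sigma_beta)
  expect_error(apply_variation(p0, c(sigma_21 = 0.1, sigma_6 = 0.2)), "tied")
  # round trip x -> x * (1+d) -> /(1+d)
  v <- c(nu_gamma_1 = 0.7, sigma_4 = -0.4)
  p4 <- apply_variation(apply_variation(p0, v), -v / (1 + v))
  expect_equal(p4$kin, p0$kin, tolerance = 1e-12)
  expect_error(apply_variation(p0, c(sigma_4 = -1)), "-100%")
  expect_error(apply_variation(p0, c(mu_M = 0.5)), "unknown")
})

test_that("zero variation predicts zero fold changes", {
  fc <- predict_fold_changes(c(sigma_12 = 0), params_sc)
  expect_lt(max(abs(fc)), 1e-8)
})

test_that("the published Type 1 deregulation reproduces its phenotype", {
  v <- unlist(table_parameter_variations()["Type1", ])
  fc <- predict_fold_changes(v, params_sc)
  expect_gt(fc[["Tbet"]], 0)     # Th1 up
  expect_lt(fc[["GATA3"]], 0)    # Th2 down
  # TGF-beta and IFN-gamma are reported even though never fitted
  expect_true(all(c("TGFb", "IFNg") %in% names(fc)))
})

test_that("the inverse fit recovers a known deregulation from its own folds", {
  truth <- c(nu_gamma_1 = -0.4, nu_alpha_1 = 0.15, nu_beta_r = 0.2,
             nu_10r = 0.2, sigma_12 = 0.25, sigma_4 = -0.2,
             sigma_21 = 0.15, sigma_6 = 0.15,
             sigma_beta = -0.12, sigma_10 = -0.12)
  targets <- predict_fold_changes(truth, params_sc)
  fit <- fit_type_parameters(targets[c("IL6", "IL10", "TNFa", "Tbet",
                                       "GATA3", "RORgt", "Foxp3")],
                             params_sc, seed = 3, restarts = 2)
  expect_lt(attr(fit, "loss"), 1e-10)
  big <- names(truth)[abs(truth) > 0.1]
  expect_lt(max(abs(fit[big] - truth[big]) / abs(truth[big])), 0.10)
  # idempotence: the forward map at the fit reproduces the targets at the
  # stored loss
  pred <- attr(fit, "predicted")
  expect_equal(unname(pred[names(targets)]), as.numeric(targets),
               tolerance = 1e-4)
})

test_that("zero targets fit to zero variation", {
  z <- stats::setNames(rep(0, 7),
                       c("IL6", "IL10", "TNFa", "Tbet", "GATA3", "RORgt", "Foxp3"))
  fit <- fit_type_parameters(z, params_sc, seed = 1, restarts = 1)
  expect_lt(max(abs(fit)), 1e-5)
})

test_that("fitting the observed Type 1 folds recovers the published sign pattern", {
  fc <- table_fold_changes()
  fit <- fit_type_parameters(
    unlist(fc["Type1", c("IL6", "IL10", "TNFa", "Tbet", "GATA3", "RORgt",
                         "Foxp3")]),
    params_sc, seed = 2, restarts = 3)
  expect_gt(fit[["sigma_12"]], 0)
  expect_lt(fit[["sigma_4"]], 0)
  expect_gt(fit[["sigma_21"]], 0)
  expect_lt(fit[["sigma_beta"]], 0)
})

test_that("targets outside the admissible band are rejected", {
  z <- stats::setNames(c(-1, rep(0, 6)),
                       c("IL6", "IL10", "TNFa", "Tbet", "GATA3", "RORgt", "Foxp3"))
  expect_error(fit_type_parameters(z, params_sc), "targets")
})
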