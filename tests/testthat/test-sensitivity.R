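test_that("Latin hypercube stratification puts one draw per bin", {
  spec <- sensitivity_spec(parameters = "mu_M", range = 0.2, n = 4,
                           seed = 1)
  draws <- lhs_sample(spec, params_pr)   # mu_M = 1 -> range [0.8, 1.2]
  bins <- findInterval(draws[, "mu_M"], c(0.8, 0.9, 1.0, 1.1, 1.2),
                       rightmost.closed = TRUE)
  expect_setequal(bins, 1:4)
})

test_that("LHS marginals are uniform and seed-reproducible", {
  spec <- sensitivity_spec(n = 2000, seed = 4)
  d1 <- lhs_sample(spec, params_sc)
  d2 <- lhs_sample(spec, params_sc)
  expect_identical(d1, d2)
  base <- unlist(params_sc$kin[spec$parameters])
  for (j in seq_along(spec$parameters)) {
    u <- (d1[, j] - 0.8 * base[j]) / (0.4 * base[j])
    expect_gte(min(u), 0); expect_lte(max(u), 1)
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("PRCC identifies perfect dependence and pure noise", {
  set.seed(10)
  X <- matrix(runif(900), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- prcc(X, cbind(y = X[, "a"]))
  expect_gt(res$prcc[res$parameter == "a"], 0.999)
  expect_lt(max(abs(res$prcc[res$parameter != "a"])), 0.15)
  # output independent of everything: coefficients small, p roughly uniform
  set.seed(11)
  pvals <- replicate(40, {
    Xn <- matrix(runif(240), 80, 3)
    colnames(Xn) <- c("a", "b", "c")
    rn <- prcc(Xn, cbind(y = runif(80)))
    rn$p_value
  })
  expect_gt(mean(pvals), 0.35); expect_lt(mean(pvals), 0.65)
})

test_that("PRCC equals the brute-force rank partial correlation", {
  set.seed(5)
  X <- matrix(runif(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 2 * X[, 2] + 0.3 * runif(8)
  res <- prcc(X, cbind(y = y))
  expect_equal(res$prcc, prcc_oracle(X, y), tolerance = 1e-12)
})

test_that("PRCC is invariant under strictly monotone transforms", {
  set.seed(6)
  X <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + 0.5 * X[, 3] + 0.1 * runif(100)
  r0 <- prcc(X, cbind(y = y))$prcc
  X2 <- X; X2[, 1] <- exp(5 * X2[, 1]); X2[, 3] <- -1 / (1 + X2[, 3])
  r1 <- prcc(X2, cbind(y = y^3))$prcc
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("constant columns yield missing coefficients", {
  set.seed(7)
  X <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  X[, 2] <- 1
  res <- prcc(X, cbind(y = X[, 1]))
  expect_true(is.na(res$prcc[res$parameter == "b"]))
})

test_that("one-dimensional sweeps reproduce the dominant Treg mechanism", {
  # raising the IL-10 arm of Treg activation suppresses Th1 monotonically
  vals <- params_sc$kin$sigma_10 * c(0.8, 0.9, 1.0, 1.1, 1.2)
  t1 <- vapply(vals, function(v) {
    kin <- params_sc$kin; kin$sigma_10 <- v
    p <- ibdimmune:::new_ibd_params(kin, params_sc$sat, "self_consistent")
    tr <- integrate_model(p, hs, horizon = 100, times = c(0, 100))
    tr[["T1"]][2L]
  }, numeric(1L))
  expect_true(all(diff(t1) < 0))
})

test_that("nominal draws return the healthy outputs", {
  spec <- sensitivity_spec(n = 12, seed = 1)
  draws <- matrix(rep(unlist(params_sc$kin[spec$parameters]), each = 12),
                  nrow = 12, dimnames = list(NULL, spec$parameters))
  outs <- evaluate_outputs(draws, params_sc, spec)
  expect_equal(unname(outs[, "T1"]), rep(hs[["T1"]], 12), tolerance = 1e-5)
  expect_equal(unname(outs[, "T2"]), rep(hs[["T2"]], 12), tolerance = 1e-5)
  expect_identical(attr(outs, "n_failed"), 0L)
  # steady-state output option polishes the endpoint to the equilibrium
  spec2 <- sensitivity_spec(n = 12, seed = 1, output_at = "steady_state")
  outs2 <- evaluate_outputs(draws, params_sc, spec2)
  expect_equal(unname(outs2[, "T1"]), rep(hs[["T1"]], 12), tolerance = 1e-9)
})
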