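# Shared fixtures: parameter sets are cheap to build, so construct fresh
# copies once per test file load.

params_sc <- default_parameters("self_consistent")
params_pr <- default_parameters("printed")
hs <- healthy_state()

# random non-negative states with realistic per-component magnitudes
random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- hs * stats::runif(15, 0, 3)
    s[sample(15, 2)] <- 0          # exercise zero components
    as_state_vector(s)
  })
}

# published PRCC table (Table-5-equivalent) used by the acceptance suite
published_prcc <- function() {
  data.frame(
    parameter = c("sigma_M_alpha", "sigma_M10", "sigma_12", "sigma_2",
                  "sigma_4", "sigma_21", "sigma_6", "sigma_beta", "sigma_10"),
    T1 = c(0.3298, 0.6264, 0.6206, 0.2257, -0.3123, 0.2756, 0.4181,
           -0.6690, -0.6866),
    T2 = c(-0.0190, -0.1448, 0.8420, 0.4404, -0.4336, 0.3192, 0.4954,
           -0.7636, -0.7858))
}

# independent PRCC oracle: partial correlation of the rank-transformed
# columns via the precision matrix of their correlation matrix
prcc_oracle <- function(X, y) {
  R <- apply(cbind(X, y), 2L, rank)
  P <- solve(stats::cor(R))
  k <- ncol(X)
  vapply(seq_len(k), function(j)
    -P[j, k + 1L] / sqrt(P[j, j] * P[k + 1L, k + 1L]), numeric(1L))
}
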