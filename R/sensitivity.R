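## Latin hypercube sampling and partial rank correlation coefficients.
##
## PRCC construction: rank-transform every parameter column and the output
## (average ranks on ties); for parameter j, regress both its ranks and the
## output's ranks on the ranks of all other parameters; the PRCC is the
## Pearson correlation of the two residual vectors. Significance uses the
## t statistic prcc * sqrt(df / (1 - prcc^2)) with df = n - 2 - (k - 1)
## (the number of conditioned variables is k - 1).

#' Sensitivity-analysis specification
#'
#' @param parameters Kinetic rates to perturb. Default: the nine macrophage
#'   and T-cell activation rates.
#' @param range Relative half-width of the uniform perturbation (0.2 =
#'   +/-20% around the baseline value).
#' @param n Number of Latin hypercube draws.
#' @param outputs State variables recorded at the end of the horizon.
#' @param horizon Evaluation horizon, weeks.
#' @param output_at `"final_time"` (record outputs after `horizon` weeks;
#'   the convention of the published analysis, whose trajectories are close
#'   to equilibrium by then) or `"steady_state"` (polish each endpoint to
#'   the exact equilibrium first).
#' @param seed Integer seed.
#' @return Object of class `ibd_sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameters = c("sigma_M_alpha", "sigma_M10",
                                            "sigma_12", "sigma_2", "sigma_4",
                                            "sigma_21", "sigma_6",
                                            "sigma_beta", "sigma_10"),
                             range = 0.2, n = 5000L,
                             outputs = c("T1", "T2"), horizon = 100,
                             output_at = c("final_time", "steady_state"),
                             seed = 1L) {
  output_at <- match.arg(output_at)
  parameters <- match.arg(parameters, .KIN_NAMES, several.ok = TRUE)
  if (!all(outputs %in% state_names()))
    stop("outputs must be state variables", call. = FALSE)
  if (range <= 0 || range >= 1) stop("range must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  if (n <= length(parameters) + 2L)
    stop("sample count must exceed the number of parameters + 2", call. = FALSE)
  structure(list(parameters = parameters, range = range, n = n,
                 outputs = outputs, horizon = horizon,
                 output_at = output_at, seed = as.integer(seed)),
            class = "ibd_sensitivity_spec")
}

#' Latin hypercube parameter sample
#'
#' Stratified uniform sample: each parameter's range is split into `n`
#' equal-probability bins with exactly one draw per bin, independently
#' permuted across parameters (`lhs::randomLHS`), then affinely mapped to
#' `baseline * (1 +/- range)`.
#'
#' @param spec A [sensitivity_spec()].
#' @param params Baseline `ibd_params` supplying the nominal values.
#' @return Matrix `n x k` of parameter values, columns named.
#' @export
lhs_sample <- function(spec, params = default_parameters()) {
  stopifnot(inherits(spec, "ibd_sensitivity_spec"))
  set.seed(spec$seed)
  u <- lhs::randomLHS(spec$n, length(spec$parameters))
  base <- unlist(params$kin[spec$parameters])
  lo <- base * (1 - spec$range)
  wid <- 2 * spec$range * base
  draws <- sweep(sweep(u, 2L, wid, "*"), 2L, lo, "+")
  colnames(draws) <- spec$parameters
  draws
}

#' Evaluate model outputs over a parameter draw table
#'
#' For each draw, integrates the model from the healthy steady state over
#' the horizon and records the requested outputs at the final time.
#' Individual integration failures yield `NA` rows (dropped listwise by
#' [prcc()] with a logged count); a failure rate above `max_failure_rate`
#' aborts.
#'
#' @param draws Matrix from [lhs_sample()].
#' @param params Baseline `ibd_params` carrying the healthy steady state.
#' @param spec The [sensitivity_spec()] (horizon, outputs).
#' @param rtol,atol Solver tolerances.
#' @param max_failure_rate Abort threshold for the failed-draw fraction.
#' @return Matrix `n x length(outputs)`, attribute `n_failed`.
#' @export
evaluate_outputs <- function(draws, params = default_parameters(),
                             spec, rtol = 1e-8, atol = 1e-12,
                             max_failure_rate = 0.01) {
  stopifnot(inherits(spec, "ibd_sensitivity_spec"))
  init <- unname(params$steady_state %||% healthy_state())
  oidx <- match(spec$outputs, state_names())
  tt <- c(0, spec$horizon)
  out <- matrix(NA_real_, nrow(draws), length(oidx),
                dimnames = list(NULL, spec$outputs))
  kin <- params$kin
  for (i in seq_len(nrow(draws))) {
    for (nm in colnames(draws)) kin[[nm]] <- draws[i, nm]
    p <- params; p$kin <- kin        # skip re-validation in the hot loop
    f <- make_rhs_function(p)
    sol <- tryCatch(
      deSolve::lsoda(init, tt, f, parms = NULL, rtol = rtol, atol = atol),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(sol) && nrow(sol) == 2L) {
      y <- pmax(sol[2L, -1L], 0)
      if (identical(spec$output_at, "steady_state")) {
        ns <- newton_polish(p, stats::setNames(y, state_names()))
        if (ns$converged) y <- unname(ns$state) else y[] <- NA_real_
      }
      out[i, ] <- y[oidx]
    }
  }
  n_failed <- sum(!stats::complete.cases(out))
  if (n_failed > max_failure_rate * nrow(draws))
    stop("sensitivity analysis aborted: ", n_failed, " of ", nrow(draws),
         " integrations failed", call. = FALSE)
  attr(out, "n_failed") <- n_failed
  out
}

#' Partial rank correlation coefficients
#'
#' @param draws Parameter matrix (`n x k`).
#' @param outputs Output matrix (`n x m`) aligned with `draws`; `NA` rows
#'   are dropped listwise.
#' @param prcc_threshold,p_threshold Significance flags: `|PRCC|` above the
#'   first and p-value below the second.
#' @return Data frame with one row per (parameter, output) pair: columns
#'   `parameter`, `output`, `prcc`, `p_value`, `significant`. A constant
#'   column yields `NA` coefficients for its pairs.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' prcc(X, cbind(y = X[, "a"]))  # PRCC(a, y) ~ +1
prcc <- function(draws, outputs, prcc_threshold = 0.5, p_threshold = 0.01) {
  outputs <- as.matrix(outputs)
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("y", seq_len(ncol(outputs)))
  keep <- stats::complete.cases(draws) & stats::complete.cases(outputs)
  X <- as.matrix(draws)[keep, , drop = FALSE]
  Y <- outputs[keep, , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n < k + 3L)
    stop("prcc needs at least k + 3 complete rows", call. = FALSE)
  df <- n - 2L - (k - 1L)
  RX <- apply(X, 2L, rank)            # average ranks on ties
  res <- vector("list", k * ncol(Y))
  ii <- 0L
  for (m in seq_len(ncol(Y))) {
    ry <- rank(Y[, m])
    for (j in seq_len(k)) {
      ii <- ii + 1L
      const <- stats::sd(X[, j]) == 0 || stats::sd(Y[, m]) == 0
      if (const) {
        res[[ii]] <- data.frame(parameter = colnames(X)[j],
                                output = colnames(Y)[m],
                                prcc = NA_real_, p_value = NA_real_,
                                significant = NA)
        next
      }
      Z <- cbind(1, RX[, -j, drop = FALSE])
      ex <- stats::lm.fit(Z, RX[, j])$residuals
      ey <- stats::lm.fit(Z, ry)$residuals
      r <- stats::cor(ex, ey)
      tstat <- r * sqrt(df / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df)
      res[[ii]] <- data.frame(parameter = colnames(X)[j],
                              output = colnames(Y)[m],
                              prcc = r, p_value = p,
                              significant = abs(r) > prcc_threshold &
                                p < p_threshold)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "n") <- n
  attr(out, "df") <- df
  out
}

#' Run the full sensitivity pipeline
#'
#' [lhs_sample()] then [evaluate_outputs()] then [prcc()].
#'
#' @inheritParams lhs_sample
#' @inheritParams evaluate_outputs
#' @return The [prcc()] data frame, with the draw and output tables
#'   attached as attributes `draws` and `outputs`.
#' @export
run_sensitivity <- function(spec = sensitivity_spec(),
                            params = default_parameters(),
                            rtol = 1e-8, atol = 1e-12) {
  draws <- lhs_sample(spec, params)
  outs <- evaluate_outputs(draws, params, spec, rtol = rtol, atol = atol)
  res <- prcc(draws, outs)
  attr(res, "draws") <- draws
  attr(res, "outputs") <- outs
  attr(res, "spec") <- spec
  res
}
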