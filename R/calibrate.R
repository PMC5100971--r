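## Steady-state parameter calibration.
##
## The calibration reproduces the published estimation procedure: set every
## cytokine half-saturation constant equal to its healthy steady-state
## concentration (so every saturation factor is exactly 1/2 at equilibrium),
## anchor the IL-6 tissue concentration and scale the other measured
## cytokines by the common mRNA-to-concentration factor lambda_c, pin the
## T-cell mRNA-to-density factor lambda_T through the IL-10 balance, and
## solve the remaining steady-state equations - which the half-saturation
## reduction renders linear in the unknown signalling maxima - in closed
## form.

#' Production rate from a single steady-state balance
#'
#' For a cytokine produced by one cell population at rate `nu` and decaying
#' at rate `delta`, the steady state gives `nu * cell = delta * cytokine`,
#' hence `nu = delta * cytokine / cell`.
#'
#' @param cell_density Source cell density, g/cm^3 (> 0).
#' @param cytokine_level Steady-state cytokine concentration, g/cm^3 (>= 0).
#' @param decay First-order decay rate, week^-1 (> 0).
#' @return Production rate, week^-1.
#' @export
#' @examples
#' rate_from_balance(3e-2, 15e-9, 349.37)  # IL-4 production by Th2: 1.75e-4
rate_from_balance <- function(cell_density, cytokine_level, decay) {
  if (cell_density <= 0) stop("cell density must be > 0", call. = FALSE)
  if (cytokine_level < 0 || decay <= 0)
    stop("cytokine level must be >= 0 and decay > 0", call. = FALSE)
  decay * cytokine_level / cell_density
}

#' Healthy reference panel of mRNA means
#'
#' Mean healthy-control mRNA levels for the three measured cytokines and the
#' four T-cell master regulators (arbitrary mRNA-count units). These are the
#' inputs to the concentration anchoring ([anchor_cytokines()]) and to the
#' lambda_T determination inside [calibrate_healthy()].
#'
#' @param means Named numeric vector with entries `IL6`, `IL10`, `TNFa`,
#'   `Tbet`, `GATA3`, `RORgt`, `Foxp3`, all > 0.
#' @return Object of class `ibd_healthy_ref` (named numeric vector).
#' @export
healthy_reference <- function(means) {
  need <- c("IL6", "IL10", "TNFa", "Tbet", "GATA3", "RORgt", "Foxp3")
  if (!all(need %in% names(means)))
    stop("healthy reference needs entries ", paste(need, collapse = ", "),
         call. = FALSE)
  means <- unlist(means)[need]
  if (any(!is.finite(means)) || any(means <= 0))
    stop("healthy reference means must be positive", call. = FALSE)
  structure(means, class = "ibd_healthy_ref")
}

#' Anchor tissue cytokine concentrations to mRNA means
#'
#' Tissue concentrations of the measured cytokines are assumed proportional
#' to their mucosal mRNA means with a common factor `lambda_c`, fixed by
#' convention through the healthy IL-6 concentration (8.00e-6 g/cm^3).
#'
#' @param ref A [healthy_reference()] panel.
#' @param il6_anchor Healthy IL-6 tissue concentration, g/cm^3.
#' @return List with `lambda_c` (g/cm^3 per mRNA unit) and `concentrations`
#'   (named vector `I6`, `Ialpha`, `I10`).
#' @export
#' @examples
#' ref <- healthy_reference(c(IL6 = 800, IL10 = 154, TNFa = 975,
#'                            Tbet = 458, GATA3 = 134, RORgt = 3370,
#'                            Foxp3 = 606))
#' anchor_cytokines(ref)$concentrations
anchor_cytokines <- function(ref, il6_anchor = 8.00e-6) {
  stopifnot(inherits(ref, "ibd_healthy_ref"))
  if (il6_anchor <= 0) stop("IL-6 anchor must be > 0", call. = FALSE)
  lambda_c <- il6_anchor / ref[["IL6"]]
  conc <- c(I6 = il6_anchor,
            Ialpha = lambda_c * ref[["TNFa"]],
            I10 = lambda_c * ref[["IL10"]])
  list(lambda_c = lambda_c, concentrations = conc)
}

## ---------------------------------------------------------------------------

#' Calibrate the model to a healthy equilibrium
#'
#' Executes the full steady-state calibration. Inputs are the known kinetic
#' rates plus either (a) a healthy mRNA reference panel, from which the
#' anchored cytokine concentrations, `lambda_T` and the four T-cell
#' densities are derived, or (b) the T-cell densities and anchored
#' concentrations directly. Under the half-saturation-equals-steady-state
#' reduction the unknowns close sequentially:
#' macrophage densities, `nu_6M`, `lambda_T` (pinned by the IL-10 balance),
#' `nu_alpha_1`, and the four signalling maxima `sigma_12`, `sigma_4`,
#' `sigma_21` (= `sigma_6`) and `sigma_beta` (= `sigma_10`), each from a
#' linear equation.
#'
#' The published macrophage basal rates are not consistent with the
#' published macrophage densities (they imply `M1 + M2 = 3.63e-2` rather
#' than `4.84e-2`); `macrophages = "anchored"` (default, required to
#' reproduce the published signalling maxima) keeps the published densities
#' and re-estimates `f1`, `f2` from the macrophage balances, while
#' `"balance"` keeps `f1`, `f2` and solves for the densities.
#'
#' @param knowns Named list of known kinetic rates (defaults to the
#'   published table values).
#' @param healthy_ref Optional [healthy_reference()] mRNA panel.
#' @param tcell_densities Named vector `T1`, `T2`, `T17`, `Tr` (g/cm^3);
#'   required if `healthy_ref` is `NULL`.
#' @param anchored Named vector `I6`, `Ialpha`, `I10` (g/cm^3); derived from
#'   `healthy_ref` when that is given.
#' @param macrophages `"anchored"` or `"balance"` (see Details).
#' @param macrophage_densities Named vector `M1`, `M2` used in anchored mode.
#' @param cytokine_targets Optional named vector of equilibrium
#'   concentrations for the six unanchored cytokines (`Igamma`, `I2`, `I4`,
#'   `I12`, `I21`, `Ibeta`). When given, the production rates of those
#'   equations are rescaled by a common per-equation factor so the target is
#'   the exact equilibrium (within-equation production ratios preserved);
#'   when `NULL` they are solved from the known production rates.
#' @param lambda_tol Maximum relative disagreement between the lambda_T
#'   values implied by the four master regulators when both `healthy_ref`
#'   and `tcell_densities` are supplied; beyond it the data are rejected.
#' @param eq8_numerator Passed to the resulting parameter object; see
#'   [default_parameters()].
#' @return Object of class `ibd_calibration`: list with `params` (an
#'   `ibd_params`, dialect `"self_consistent"`, carrying the calibrated
#'   steady state), `estimates` (the estimated rates plus `f1`, `f2`,
#'   `lambda_c`, `lambda_T`), `steady_state`, `residuals` (per-equation
#'   relative residuals at the calibrated equilibrium) and `dialect`.
#' @export
#' @examples
#' cal <- calibrate_healthy()
#' round(cal$estimates[c("sigma_12", "sigma_4", "sigma_21", "sigma_beta")], 2)
calibrate_healthy <- function(knowns = .printed_kinetics(),
                              healthy_ref = NULL,
                              tcell_densities = if (is.null(healthy_ref))
                                healthy_state()[c("T1", "T2", "T17", "Tr")],
                              anchored = if (is.null(healthy_ref))
                                healthy_state()[c("I6", "Ialpha", "I10")],
                              macrophages = c("anchored", "balance"),
                              macrophage_densities = c(M1 = 2.34e-2, M2 = 2.50e-2),
                              cytokine_targets = healthy_state()[c("Igamma", "I2", "I4", "I12", "I21", "Ibeta")],
                              lambda_tol = 0.01,
                              eq8_numerator = "I2") {
  macrophages <- match.arg(macrophages)
  kin <- utils::modifyList(.printed_kinetics(), as.list(knowns))
  gam <- .printed_saturations()
  lambda_c <- NA_real_
  lambda_T <- NA_real_

  ## -- macrophage block (saturation factors are 1/2 at the equilibrium) ----
  a11 <- kin$sigma_M_beta / 2 + kin$mu_M      # d(M1): -a11*M1 + a12*M2 + b1
  a12 <- kin$sigma_M_gamma / 2
  b1 <- (kin$f1 + kin$sigma_M_alpha / 2) * kin$M0
  b2 <- (kin$f2 + kin$sigma_M10 / 2) * kin$M0
  if (macrophages == "anchored") {
    M1 <- macrophage_densities[["M1"]]; M2 <- macrophage_densities[["M2"]]
    kin$f1 <- (a11 * M1 - a12 * M2) / kin$M0 - kin$sigma_M_alpha / 2
    kin$f2 <- ((a12 + kin$mu_M) * M2 - (a11 - kin$mu_M) * M1) / kin$M0 -
      kin$sigma_M10 / 2
    if (kin$f1 < 0 || kin$f2 < 0)
      stop("calibration error: anchored macrophage densities imply negative ",
           "basal activation rates", call. = FALSE)
  } else {
    A <- matrix(c(a11, -(a11 - kin$mu_M), -a12, a12 + kin$mu_M), 2L, 2L)
    m <- solve(A, c(b1, b2))
    M1 <- m[1L]; M2 <- m[2L]
  }
  M <- M1 + M2

  ## -- anchored concentrations and cell densities --------------------------
  if (!is.null(healthy_ref)) {
    anc <- anchor_cytokines(healthy_ref)
    lambda_c <- anc$lambda_c
    if (is.null(anchored)) anchored <- anc$concentrations
    ## lambda_T closes through the IL-10 balance: the only steady-state
    ## equation linking a known production rate to a T-cell density whose
    ## cytokine is anchored.
    lambda_T <- (kin$delta_10 * anchored[["I10"]] - kin$nu_10M * M2) /
      (kin$nu_10r * (1 + kin$n_2r / 2) * healthy_ref[["Foxp3"]])
    if (!is.finite(lambda_T) || lambda_T <= 0)
      stop("calibration error: IL-10 balance gives non-positive lambda_T",
           call. = FALSE)
    implied <- lambda_T * healthy_ref[c("Tbet", "GATA3", "RORgt", "Foxp3")]
    names(implied) <- c("T1", "T2", "T17", "Tr")
    if (!is.null(tcell_densities)) {
      lam4 <- unlist(tcell_densities)[c("T1", "T2", "T17", "Tr")] /
        healthy_ref[c("Tbet", "GATA3", "RORgt", "Foxp3")]
      if ((max(lam4) - min(lam4)) / mean(lam4) > lambda_tol)
        stop("data error: lambda_T implied by the four master regulators ",
             "disagrees by more than ", lambda_tol * 100, "%", call. = FALSE)
      lambda_T <- mean(lam4)
    } else {
      tcell_densities <- implied
    }
  }
  if (is.null(tcell_densities) || is.null(anchored))
    stop("calibration needs either healthy_ref or both tcell_densities and ",
         "anchored concentrations", call. = FALSE)
  tc <- unlist(tcell_densities)[c("T1", "T2", "T17", "Tr")]
  anchored <- unlist(anchored)[c("I6", "Ialpha", "I10")]
  if (any(tc <= 0) || any(anchored <= 0))
    stop("densities and anchored concentrations must be positive", call. = FALSE)
  T1 <- tc[["T1"]]; T2 <- tc[["T2"]]; T17 <- tc[["T17"]]; Tr <- tc[["Tr"]]

  ## -- production rates estimated from anchored balances -------------------
  kin$nu_6M <- rate_from_balance(M1, anchored[["I6"]], kin$delta_6)
  kin$nu_alpha_1 <- (kin$delta_alpha * anchored[["Ialpha"]] -
                       kin$nu_alpha_M * M1) / T1
  if (kin$nu_alpha_1 < 0)
    stop("calibration error: TNF-alpha balance gives negative nu_alpha_1",
         call. = FALSE)

  ## -- signalling maxima: linear under the half-saturation reduction ------
  h2 <- inhibit(T2, gam$gamma_2); hr1 <- inhibit(Tr, gam$gamma_r1)
  h1 <- inhibit(T1, gam$gamma_1); hr2 <- inhibit(Tr, gam$gamma_r2)
  hr17 <- inhibit(Tr, gam$gamma_r17); h17 <- inhibit(T17, gam$gamma_17)
  kin$sigma_12 <- (kin$mu_1 * T1 / (h2 * hr1) - kin$sigma_2 * T1 / 2) * 4 / M
  kin$sigma_4 <- kin$mu_2 * T2 / (M * h1 * hr2 / 2)
  kin$sigma_21 <- kin$sigma_6 <- 8 * kin$mu_17 * T17 / (M * hr17)
  kin$sigma_beta <- kin$sigma_10 <- 4 * kin$mu_r * Tr / (M * h17)
  if (kin$sigma_12 < 0)
    stop("calibration error: Th1 balance gives negative sigma_12", call. = FALSE)

  ## -- remaining steady concentrations and production rescaling -----------
  solve_cyt <- c(
    Igamma = (kin$nu_gamma_M * M1 + kin$nu_gamma_1 * T1) / kin$delta_gamma,
    I2 = kin$nu_21 * T1 / kin$delta_2,
    I4 = (kin$nu_4M * M2 + kin$nu_42 * T2) / kin$delta_4,
    I12 = kin$nu_12M * M1 / 2 / kin$delta_12,
    I21 = kin$nu_2117 * T17 / kin$delta_21,
    Ibeta = (kin$nu_beta_M * M2 + kin$nu_beta_r * Tr) / kin$delta_beta)
  if (!is.null(cytokine_targets)) {
    tgt <- unlist(cytokine_targets)[names(solve_cyt)]
    scl <- tgt / solve_cyt
    kin$nu_gamma_M <- kin$nu_gamma_M * scl[["Igamma"]]
    kin$nu_gamma_1 <- kin$nu_gamma_1 * scl[["Igamma"]]
    kin$nu_21 <- kin$nu_21 * scl[["I2"]]
    kin$nu_4M <- kin$nu_4M * scl[["I4"]]
    kin$nu_42 <- kin$nu_42 * scl[["I4"]]
    kin$nu_12M <- kin$nu_12M * scl[["I12"]]
    kin$nu_2117 <- kin$nu_2117 * scl[["I21"]]
    kin$nu_beta_M <- kin$nu_beta_M * scl[["Ibeta"]]
    kin$nu_beta_r <- kin$nu_beta_r * scl[["Ibeta"]]
    solve_cyt <- tgt
  }
  ## the IL-10 equation must balance at the anchored concentration; rescale
  ## its production pair by the (small) residual factor
  prod10 <- kin$nu_10M * M2 + kin$nu_10r * (1 + kin$n_2r / 2) * Tr
  scl10 <- kin$delta_10 * anchored[["I10"]] / prod10
  kin$nu_10M <- kin$nu_10M * scl10
  kin$nu_10r <- kin$nu_10r * scl10

  ss <- as_state_vector(c(
    M1 = M1, M2 = M2, T1 = T1, T2 = T2, T17 = T17, Tr = Tr,
    Igamma = solve_cyt[["Igamma"]], I2 = solve_cyt[["I2"]],
    I4 = solve_cyt[["I4"]], I6 = anchored[["I6"]], I10 = anchored[["I10"]],
    I12 = solve_cyt[["I12"]], I21 = solve_cyt[["I21"]],
    Ialpha = anchored[["Ialpha"]], Ibeta = solve_cyt[["Ibeta"]]))

  ## half-saturations equal the calibrated steady state; gamma constants
  ## are kept at their published values
  sat <- gam
  sat$zeta_gamma <- ss[["Igamma"]]; sat$zeta_2 <- ss[["I2"]]
  sat$zeta_4 <- ss[["I4"]]; sat$zeta_6 <- ss[["I6"]]
  sat$zeta_10 <- ss[["I10"]]; sat$zeta_12 <- ss[["I12"]]
  sat$zeta_21 <- ss[["I21"]]; sat$zeta_alpha <- ss[["Ialpha"]]
  sat$zeta_beta <- ss[["Ibeta"]]

  params <- new_ibd_params(kin, sat, dialect = "self_consistent",
                           eq8_numerator = eq8_numerator, steady_state = ss)
  resid <- relative_residuals(params, ss)
  if (max(abs(resid)) > 1e-8)
    stop("calibration error: steady-state residuals exceed tolerance; ",
         "worst equation: ", names(which.max(abs(resid))), " = ",
         format(max(abs(resid))), call. = FALSE)

  est <- c(nu_6M = kin$nu_6M, nu_alpha_1 = kin$nu_alpha_1,
           sigma_12 = kin$sigma_12, sigma_4 = kin$sigma_4,
           sigma_21 = kin$sigma_21, sigma_6 = kin$sigma_6,
           sigma_beta = kin$sigma_beta, sigma_10 = kin$sigma_10,
           f1 = kin$f1, f2 = kin$f2,
           lambda_c = lambda_c, lambda_T = lambda_T)
  structure(list(params = params, estimates = est, steady_state = ss,
                 residuals = resid, dialect = "self_consistent"),
            class = "ibd_calibration")
}

#' Self-consistent default parameter set
#'
#' Runs [calibrate_healthy()] with the published healthy state as the
#' anchored equilibrium: the published cell densities and anchored cytokine
#' concentrations are kept verbatim, the estimated rates are re-derived at
#' full precision and the per-equation production rescalings make the
#' published healthy state an exact fixed point of the model.
#'
#' @inheritParams default_parameters
#' @return An `ibd_params` object carrying the steady state.
#' @export
calibrate_self_consistent <- function(eq8_numerator = c("I2", "Igamma")) {
  eq8_numerator <- match.arg(eq8_numerator)
  hs <- healthy_state()
  cal <- calibrate_healthy(
    tcell_densities = hs[c("T1", "T2", "T17", "Tr")],
    anchored = hs[c("I6", "Ialpha", "I10")],
    macrophages = "anchored",
    macrophage_densities = hs[c("M1", "M2")],
    cytokine_targets = hs[c("Igamma", "I2", "I4", "I12", "I21", "Ibeta")],
    eq8_numerator = eq8_numerator)
  cal$params
}

#' @export
print.ibd_calibration <- function(x, ...) {
  cat("<ibd_calibration> dialect:", x$dialect, "\n")
  cat("  estimated rates (week^-1):\n")
  print(signif(x$estimates, 4))
  cat("  max |relative residual|:", format(max(abs(x$residuals)), digits = 3), "\n")
  invisible(x)
}

#' Per-equation relative residuals at a state
#'
#' Residual of each equation normalised by its first-order loss term
#' (`decay rate x concentration`), so that for a pure production-decay
#' cytokine equation the value equals the relative error between the implied
#' and the actual steady-state concentration.
#'
#' @param params An `ibd_params`.
#' @param state State at which to evaluate.
#' @return Named numeric vector of signed relative residuals.
#' @export
relative_residuals <- function(params, state) {
  state <- as_state_vector(state)
  k <- params$kin
  loss_rate <- c(M1 = k$mu_M, M2 = k$mu_M, T1 = k$mu_1, T2 = k$mu_2,
                 T17 = k$mu_17, Tr = k$mu_r,
                 Igamma = k$delta_gamma, I2 = k$delta_2, I4 = k$delta_4,
                 I6 = k$delta_6, I10 = k$delta_10, I12 = k$delta_12,
                 I21 = k$delta_21, Ialpha = k$delta_alpha, Ibeta = k$delta_beta)
  r <- model_rhs(state, params)
  r / (loss_rate[state_names()] * pmax(state, 1e-300))
}

#' Consistency audit of the published parameter tables
#'
#' Evaluates every steady-state balance at the published healthy state with
#' the published kinetic rates and reports the relative residuals
#' ([relative_residuals()]), flagging equations whose residual exceeds
#' `flag_above`. The published tables are internally inconsistent: the
#' IFN-gamma, IL-2, IL-6, IL-12, IL-4 and M2 balances fail by 5% to more
#' than an order of magnitude, while IL-10, IL-21, TNF-alpha and the T-cell
#' balances hold to within ~2%.
#'
#' @param params Parameter object, default the printed dialect.
#' @param state State to audit, default the published healthy state.
#' @param flag_above Relative-residual threshold for the flag column.
#' @return Data frame with columns `equation`, `residual`, `flagged`.
#' @export
#' @examples
#' audit <- audit_printed_parameters()
#' subset(audit, flagged)
audit_printed_parameters <- function(params = default_parameters("printed"),
                                     state = healthy_state(),
                                     flag_above = 0.05) {
  resid <- relative_residuals(params, state)
  data.frame(equation = names(resid),
             residual = unname(resid),
             flagged = abs(unname(resid)) > flag_above,
             row.names = NULL)
}
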