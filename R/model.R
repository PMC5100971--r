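## Right-hand side of the 15-equation immune network.
##
## Structure of the network (all activation terms are Michaelis-Menten
## saturations, all cell-cell inhibitions are 1/(1 + x/c) factors):
##   - cytokines are produced linearly by their source cells and decay
##     first-order; IL-10 production by Treg is amplified by IL-2 receptor
##     occupancy; IL-12 production is suppressed by IL-10;
##   - M0 -> M1 activation by TNF-alpha, M0 -> M2 by IL-10; M1 <-> M2
##     transitions by TGF-beta and IFN-gamma (these conserve M1 + M2);
##   - Th1 is driven by IL-12 (IL-10-suppressed) and IL-2 self-amplification,
##     inhibited by Th2 and Treg; Th2 by IL-4, inhibited by Th1 and Treg;
##     Th17 by IL-21 + IL-6 gated by TGF-beta, resisted by IFN-gamma and
##     IL-4, inhibited by Treg; Treg by TGF-beta + IL-10 gated by IL-2 and
##     damped by TNF-alpha, inhibited by Th17.

#' Saturating activation fraction
#'
#' `saturate(x, zeta) = x / (zeta + x)`, the occupancy of a receptor with
#' half-saturation constant `zeta` at ligand concentration `x`.
#'
#' @param x Concentration (>= 0), g/cm^3. Vectorised.
#' @param zeta Half-saturation constant (> 0), g/cm^3.
#' @return Value in `[0, 1)`.
#' @export
#' @examples
#' saturate(9.75e-6, 9.75e-6)  # 0.5 at the half-saturation point
saturate <- function(x, zeta) {
  if (any(x < 0)) stop("saturate(): concentration must be >= 0", call. = FALSE)
  if (any(zeta <= 0)) stop("saturate(): half-saturation must be > 0", call. = FALSE)
  x / (zeta + x)
}

#' Inhibition fraction
#'
#' `inhibit(x, c) = 1 / (1 + x/c)`: the multiplicative damping exerted by an
#' inhibitor at level `x` with inhibition constant `c`.
#'
#' @param x Inhibitor concentration or cell density (>= 0). Vectorised.
#' @param c Inhibition constant (> 0).
#' @return Value in `(0, 1]`.
#' @export
inhibit <- function(x, c) {
  if (any(x < 0)) stop("inhibit(): level must be >= 0", call. = FALSE)
  if (any(c <= 0)) stop("inhibit(): constant must be > 0", call. = FALSE)
  1 / (1 + x / c)
}

#' Time derivatives of the immune network state
#'
#' Evaluates the right-hand side of the 15 differential equations at a given
#' state. Units: g/cm^3 per week.
#'
#' @param state State vector (see [state_names()]); must be non-negative.
#' @param params An `ibd_params` object (see [default_parameters()]).
#' @param clamp_tnfa If `TRUE`, TNF-alpha is held at zero (its derivative is
#'   removed and every TNF-alpha-dependent term evaluated at 0); used by the
#'   blockade experiment.
#' @return Named derivative vector of length 15.
#' @export
#' @examples
#' p <- default_parameters()
#' max(abs(model_rhs(healthy_state(), p)))  # ~0 at the calibrated equilibrium
model_rhs <- function(state, params, clamp_tnfa = FALSE) {
  state <- as_state_vector(state)
  f <- make_rhs_function(params, clamp_tnfa = clamp_tnfa)
  d <- f(0, unname(state), NULL)[[1L]]
  names(d) <- state_names()
  d
}

## Fast closure used by the integrator and steady-state solver: all
## parameters are bound as locals once, states addressed by position.
## Index map: 1 M1, 2 M2, 3 T1, 4 T2, 5 T17, 6 Tr, 7 Igamma, 8 I2, 9 I4,
## 10 I6, 11 I10, 12 I12, 13 I21, 14 Ialpha, 15 Ibeta.
make_rhs_function <- function(params, clamp_tnfa = FALSE) {
  stopifnot(inherits(params, "ibd_params"))
  k <- params$kin; s <- params$sat
  eq8_gamma <- identical(params$eq8_numerator, "Igamma")

  f1 <- k$f1; f2 <- k$f2; M0 <- k$M0; mu_M <- k$mu_M
  sMa <- k$sigma_M_alpha; sMg <- k$sigma_M_gamma
  sM10 <- k$sigma_M10; sMb <- k$sigma_M_beta
  ngM <- k$nu_gamma_M; ng1 <- k$nu_gamma_1; n21 <- k$nu_21
  n4M <- k$nu_4M; n42 <- k$nu_42; n6M <- k$nu_6M
  n10M <- k$nu_10M; n10r <- k$nu_10r; n12M <- k$nu_12M; n2117 <- k$nu_2117
  naM <- k$nu_alpha_M; na1 <- k$nu_alpha_1
  nbM <- k$nu_beta_M; nbr <- k$nu_beta_r; n2r <- k$n_2r
  dg <- k$delta_gamma; d2 <- k$delta_2; d4 <- k$delta_4; d6 <- k$delta_6
  d10 <- k$delta_10; d12 <- k$delta_12; d21 <- k$delta_21
  da <- k$delta_alpha; db <- k$delta_beta
  s12 <- k$sigma_12; s2 <- k$sigma_2; s4 <- k$sigma_4
  s21 <- k$sigma_21; s6 <- k$sigma_6; sb <- k$sigma_beta; s10 <- k$sigma_10
  mu1 <- k$mu_1; mu2 <- k$mu_2; mu17 <- k$mu_17; mur <- k$mu_r
  zg <- s$zeta_gamma; z2 <- s$zeta_2; z4 <- s$zeta_4; z6 <- s$zeta_6
  z10 <- s$zeta_10; z12 <- s$zeta_12; z21 <- s$zeta_21
  za <- s$zeta_alpha; zb <- s$zeta_beta
  g1 <- s$gamma_1; g2 <- s$gamma_2; g17 <- s$gamma_17
  gr1 <- s$gamma_r1; gr2 <- s$gamma_r2; gr17 <- s$gamma_r17

  function(t, y, parms) {
    y[y < 0] <- 0                       # guard against solver under-shoot
    if (clamp_tnfa) y[14L] <- 0
    M <- y[1L] + y[2L]
    sat_a <- y[14L] / (za + y[14L]); sat_g <- y[7L] / (zg + y[7L])
    sat_b <- y[15L] / (zb + y[15L]); sat_10 <- y[11L] / (z10 + y[11L])
    sat_2 <- y[8L] / (z2 + y[8L]); sat_12 <- y[12L] / (z12 + y[12L])
    sat_4 <- y[9L] / (z4 + y[9L]); sat_21 <- y[13L] / (z21 + y[13L])
    sat_6 <- y[10L] / (z6 + y[10L])
    h10 <- 1 / (1 + y[11L] / z10)
    trans_b <- sMb * sat_b; trans_g <- sMg * sat_g
    occ2 <- if (eq8_gamma) y[7L] / (z2 + y[8L]) else sat_2

    d <- numeric(15L)
    d[1L] <- (f1 + sMa * sat_a) * M0 - trans_b * y[1L] + trans_g * y[2L] - mu_M * y[1L]
    d[2L] <- (f2 + sM10 * sat_10) * M0 + trans_b * y[1L] - trans_g * y[2L] - mu_M * y[2L]
    d[3L] <- (s12 * sat_12 * h10 * M + s2 * sat_2 * y[3L]) /
      ((1 + y[4L] / g2) * (1 + y[6L] / gr1)) - mu1 * y[3L]
    d[4L] <- s4 * sat_4 * M / ((1 + y[3L] / g1) * (1 + y[6L] / gr2)) - mu2 * y[4L]
    d[5L] <- (s21 * sat_21 + s6 * sat_6) * sat_b * M /
      ((1 + y[7L] / zg) * (1 + y[9L] / z4)) / (1 + y[6L] / gr17) - mu17 * y[5L]
    d[6L] <- (sb * sat_b + s10 * sat_10) * sat_2 * M / (1 + y[14L] / za) /
      (1 + y[5L] / g17) - mur * y[6L]
    d[7L] <- ngM * y[1L] + ng1 * y[3L] - dg * y[7L]
    d[8L] <- n21 * y[3L] - d2 * y[8L]
    d[9L] <- n4M * y[2L] + n42 * y[4L] - d4 * y[9L]
    d[10L] <- n6M * y[1L] - d6 * y[10L]
    d[11L] <- n10M * y[2L] + n10r * (1 + n2r * occ2) * y[6L] - d10 * y[11L]
    d[12L] <- n12M * y[1L] * h10 - d12 * y[12L]
    d[13L] <- n2117 * y[5L] - d21 * y[13L]
    d[14L] <- if (clamp_tnfa) 0 else naM * y[1L] + na1 * y[3L] - da * y[14L]
    d[15L] <- nbM * y[2L] + nbr * y[6L] - db * y[15L]
    list(d)
  }
}

#' Finite-difference Jacobian of the model right-hand side
#'
#' Central-difference Jacobian of [model_rhs()] at a state; used for
#' structural checks and by the Newton steady-state polish.
#'
#' @inheritParams model_rhs
#' @param typical Typical magnitudes used to scale the step per component
#'   (defaults to the healthy steady state).
#' @return 15 x 15 matrix, rows = equations, columns = states.
#' @export
model_jacobian <- function(state, params, clamp_tnfa = FALSE,
                           typical = healthy_state()) {
  state <- as_state_vector(state)
  f <- make_rhs_function(params, clamp_tnfa = clamp_tnfa)
  y <- unname(state)
  typ <- pmax(unname(typical), 1e-15)
  J <- matrix(0, 15L, 15L, dimnames = list(state_names(), state_names()))
  for (j in 1:15) {
    h <- max(abs(y[j]), typ[j]) * 1e-6
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- max(ym[j] - h, 0)
    J[, j] <- (f(0, yp, NULL)[[1L]] - f(0, ym, NULL)[[1L]]) / (yp[j] - ym[j])
  }
  J
}
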