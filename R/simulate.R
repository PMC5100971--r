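## Trajectory integration, steady-state location, TNF-alpha blockade.

#' Integrate the immune network ODE system
#'
#' Stiff-capable adaptive integration (`deSolve::lsoda`) of the 15-equation
#' system.
#'
#' @param params An `ibd_params` object.
#' @param init Initial state (non-negative, length 15).
#' @param horizon Integration horizon in weeks (> 0).
#' @param times Optional output time grid; defaults to 201 equally spaced
#'   points on `[0, horizon]`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param clamp_tnfa Hold TNF-alpha at zero throughout (blockade dynamics).
#' @return Object of class `ibd_trajectory`: data frame with a `time` column
#'   (weeks) and one column per state, with attributes `dialect` and
#'   `solver` (tolerances and step count).
#' @export
#' @examples
#' p <- default_parameters()
#' tr <- integrate_model(p, 1.5 * healthy_state(), horizon = 50)
#' tail(tr, 1)
integrate_model <- function(params, init, horizon, times = NULL,
                            rtol = 1e-8, atol = 1e-12, clamp_tnfa = FALSE) {
  stopifnot(inherits(params, "ibd_params"))
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  init <- as_state_vector(init)
  if (clamp_tnfa) init["Ialpha"] <- 0
  if (is.null(times)) times <- seq(0, horizon, length.out = 201L)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  f <- make_rhs_function(params, clamp_tnfa = clamp_tnfa)
  out <- deSolve::lsoda(unname(init), times, f, parms = NULL,
                        rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (nrow(out) < length(times))
    stop("integration error: solver stopped at t = ",
         format(out[nrow(out), 1L]), " weeks; final state: ",
         paste(format(out[nrow(out), -1L], digits = 3), collapse = " "),
         call. = FALSE)
  traj <- as.data.frame(out)
  names(traj) <- c("time", state_names())
  ## clip solver undershoot (bounded by atol) at zero
  traj[-1L][traj[-1L] < 0] <- 0
  structure(traj, class = c("ibd_trajectory", "data.frame"),
            dialect = params$dialect,
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          steps = diagn[3L]))
}

final_state <- function(traj) {
  as_state_vector(unlist(traj[nrow(traj), state_names()]))
}

#' Locate a steady state of the model
#'
#' Integrates from `init` for `horizon` weeks to approach the physically
#' reached attractor, then polishes the endpoint with a damped Newton
#' iteration on the right-hand side. The Newton step is solved in scaled
#' variables (the state spans 11 orders of magnitude) and is accepted only
#' while the residual decreases and the state stays non-negative. If the
#' polish fails to converge, integration is extended (to
#' `fallback_horizon`) and the polish retried; a persistent failure, a
#' negative component, or a polish that moves the state away from the
#' integrated endpoint by more than `max_polish_shift` (a sign that Newton
#' jumped to a different, dynamically unreachable root) is an error.
#'
#' @inheritParams integrate_model
#' @param horizon Initial integration span, weeks.
#' @param fallback_horizon Extended span used if the polish does not
#'   converge after the initial integration.
#' @param tol Maximum relative residual (per equation, scaled by its loss
#'   term) accepted as a steady state.
#' @param max_polish_shift Maximum relative movement allowed during the
#'   Newton polish.
#' @return Named steady-state vector.
#' @export
find_steady_state <- function(params, init, horizon = 100,
                              fallback_horizon = 500, tol = 1e-10,
                              rtol = 1e-8, atol = 1e-12,
                              clamp_tnfa = FALSE, max_polish_shift = 0.2) {
  init <- as_state_vector(init)
  for (h in unique(c(horizon, fallback_horizon))) {
    traj <- integrate_model(params, init, horizon = h,
                            times = c(0, h), rtol = rtol, atol = atol,
                            clamp_tnfa = clamp_tnfa)
    y0 <- final_state(traj)
    ns <- newton_polish(params, y0, clamp_tnfa = clamp_tnfa, tol = tol)
    if (ns$converged) {
      shift <- max(abs(ns$state - y0) / pmax(abs(y0), 1e-12 * max(y0)))
      if (shift <= max_polish_shift) return(ns$state)
    }
    init <- y0
  }
  stop("steady-state search did not converge after ", fallback_horizon,
       " weeks; last residual: ", format(ns$residual, digits = 3),
       call. = FALSE)
}

## Damped Newton iteration on rhs = 0, in variables scaled by the healthy
## steady state. Residuals are normalised per equation by max(|y|, typical).
newton_polish <- function(params, init, clamp_tnfa = FALSE, tol = 1e-10,
                          maxit = 50L) {
  nm <- state_names()
  free <- if (clamp_tnfa) setdiff(nm, "Ialpha") else nm
  idx <- match(free, nm)
  typ <- pmax(unname(healthy_state())[idx], 1e-15)
  f <- make_rhs_function(params, clamp_tnfa = clamp_tnfa)
  y <- unname(as_state_vector(init))
  if (clamp_tnfa) y[14L] <- 0
  res_norm <- function(yy) {
    r <- f(0, yy, NULL)[[1L]][idx]
    max(abs(r) / pmax(abs(yy[idx]), typ))
  }
  for (it in seq_len(maxit)) {
    r <- f(0, y, NULL)[[1L]][idx]
    scale <- pmax(abs(y[idx]), typ)
    if (max(abs(r) / scale) < tol)
      return(list(state = stats::setNames(y, nm), converged = TRUE,
                  residual = max(abs(r) / scale), iterations = it))
    J <- matrix(0, length(idx), length(idx))
    for (j in seq_along(idx)) {
      h <- max(abs(y[idx[j]]), typ[j]) * 1e-7
      yp <- y; yp[idx[j]] <- yp[idx[j]] + h
      J[, j] <- (f(0, yp, NULL)[[1L]][idx] - r) / h
    }
    Js <- sweep(sweep(J, 2L, typ, "*"), 1L, scale, "/")
    u <- tryCatch(solve(Js, -r / scale), error = function(e) NULL)
    if (is.null(u)) break
    step <- typ * u
    lam <- 1
    repeat {
      yn <- y
      yn[idx] <- pmax(y[idx] + lam * step, 0)
      if (res_norm(yn) < max(abs(r) / scale) || lam < 1e-6) break
      lam <- lam / 2
    }
    y <- yn
  }
  r <- f(0, y, NULL)[[1L]][idx]
  list(state = stats::setNames(y, nm), converged = FALSE,
       residual = max(abs(r) / pmax(abs(y[idx]), typ)), iterations = maxit)
}

#' Simulate TNF-alpha blockade
#'
#' Models complete anti-TNF therapy by fixing the tissue TNF-alpha
#' concentration at zero: the TNF-alpha equation is removed and every
#' TNF-alpha-dependent term is evaluated at 0, so the macrophage activation
#' term by TNF-alpha vanishes and the TNF-alpha damping of Treg activation
#' is lifted. The post-blockade steady state of the remaining 14 equations
#' is located from the pre-treatment state.
#'
#' @param params Parameter set describing the (diseased) subject.
#' @param diseased_ss Pre-treatment steady state of `params`.
#' @param healthy_ss Healthy reference state used for the second fold-change
#'   convention; defaults to the calibrated steady state carried by
#'   `params`, or [healthy_state()].
#' @param dose Fraction of TNF-alpha remaining under treatment. The default
#'   0 is the complete blockade; intermediate values scale the TNF-alpha
#'   production rates by `dose` instead of clamping (`method` is forced to
#'   `"production_limit"` when `dose > 0`).
#' @param method `"clamp"` (fix the concentration at zero; default) or
#'   `"production_limit"` (set the TNF-alpha production rates to `dose`
#'   times their value and solve the full system; at `dose = 0` the two
#'   must agree, which is used as an internal cross-check).
#' @return Object of class `ibd_blockade`: list with `pre`, `post`,
#'   `change_vs_pre` and `change_vs_healthy` (fractional changes; the
#'   healthy-baseline convention divides the post-pre difference by the
#'   healthy level), plus `dose` and `method`.
#' @export
#' @examples
#' p <- default_parameters()
#' b <- simulate_blockade(p, healthy_state())
#' b$change_vs_pre["Tr"]  # Treg rises when the TNF-alpha damping is lifted
simulate_blockade <- function(params, diseased_ss, healthy_ss = NULL,
                              dose = 0, method = c("clamp", "production_limit")) {
  method <- match.arg(method)
  diseased_ss <- as_state_vector(diseased_ss)
  if (is.null(healthy_ss))
    healthy_ss <- params$steady_state %||% healthy_state()
  healthy_ss <- as_state_vector(healthy_ss)
  if (dose < 0 || dose > 1) stop("dose must be in [0, 1]", call. = FALSE)
  if (dose > 0) method <- "production_limit"

  if (method == "clamp") {
    init <- diseased_ss; init["Ialpha"] <- 0
    post <- find_steady_state(params, init, clamp_tnfa = TRUE)
  } else {
    kin <- params$kin
    kin$nu_alpha_M <- kin$nu_alpha_M * dose
    kin$nu_alpha_1 <- kin$nu_alpha_1 * dose
    p2 <- new_ibd_params(kin, params$sat, dialect = params$dialect,
                         eq8_numerator = params$eq8_numerator,
                         steady_state = params$steady_state)
    post <- find_steady_state(p2, diseased_ss)
  }
  structure(list(
    pre = diseased_ss, post = post,
    change_vs_pre = (post - diseased_ss) / pmax(diseased_ss, 1e-300),
    change_vs_healthy = (post - diseased_ss) / pmax(healthy_ss, 1e-300),
    dose = dose, method = method), class = "ibd_blockade")
}

#' @export
print.ibd_blockade <- function(x, ...) {
  cat("<ibd_blockade> method:", x$method, "dose:", x$dose, "\n")
  cells <- c("T1", "T2", "T17", "Tr")
  tab <- rbind(`% change vs pre-treatment` = 100 * x$change_vs_pre[cells],
               `% change vs healthy` = 100 * x$change_vs_healthy[cells])
  print(round(tab, 1))
  invisible(x)
}
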