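## Parameter and state-space definitions for the gut mucosal immune model.
##
## Units are g/cm^3 for all densities and concentrations and week^-1 for all
## rates; there is no unit-conversion layer.

#' Names and ordering of the model state vector
#'
#' The model tracks 15 concentrations: two activated macrophage pools,
#' four T-cell pools, and nine cytokines. The ordering is fixed and used by
#' every vector interface in the package:
#' `M1, M2, T1, T2, T17, Tr, Igamma, I2, I4, I6, I10, I12, I21, Ialpha, Ibeta`
#' (M1/M2 macrophages; Th1, Th2, Th17, Treg cells; IFN-gamma, IL-2, IL-4,
#' IL-6, IL-10, IL-12, IL-21, TNF-alpha, TGF-beta).
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' state_names()
state_names <- function() {
  c("M1", "M2", "T1", "T2", "T17", "Tr",
    "Igamma", "I2", "I4", "I6", "I10", "I12", "I21", "Ialpha", "Ibeta")
}

.CYTOKINES <- c("Igamma", "I2", "I4", "I6", "I10", "I12", "I21", "Ialpha", "Ibeta")
.TCELLS <- c("T1", "T2", "T17", "Tr")

#' Validate and normalise a model state vector
#'
#' @param x Numeric vector of length 15, named or in the canonical order of
#'   [state_names()].
#' @return Named numeric vector in canonical order.
#' @export
as_state_vector <- function(x) {
  nm <- state_names()
  if (!is.numeric(x) || length(x) != 15L)
    stop("state vector must be numeric of length 15", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm))
      stop("state vector names must be exactly ", paste(nm, collapse = ", "),
           call. = FALSE)
    x <- x[nm]
  } else {
    names(x) <- nm
  }
  if (any(!is.finite(x))) stop("state vector must be finite", call. = FALSE)
  if (any(x < 0)) stop("state vector must be non-negative", call. = FALSE)
  x
}

#' Total macrophage density
#'
#' @param state A state vector (see [as_state_vector()]).
#' @return `M1 + M2`.
#' @export
total_macrophages <- function(state) {
  state <- as_state_vector(state)
  unname(state["M1"] + state["M2"])
}

## ---------------------------------------------------------------------------
## Published parameter values (kinetic rates, inhibition and half-saturation
## constants, healthy steady state). These are the package's "printed"
## dialect; see calibrate_self_consistent() for the runnable equilibrium
## dialect.

.printed_kinetics <- function() {
  list(
    ## macrophages
    f1 = 1, f2 = 10,
    sigma_M_alpha = 2.4, sigma_M_gamma = 24, sigma_M10 = 24, sigma_M_beta = 24,
    M0 = 1.5e-3, mu_M = 1,
    ## cytokine production
    nu_gamma_M = 8.2e-6, nu_gamma_1 = 4.1e-5,
    nu_4M = 5.83e-5, nu_42 = 1.75e-4,
    nu_6M = 3.63e-3,
    nu_10M = 3.72e-4, nu_10r = 1.12e-3,
    nu_12M = 2.65e-4,
    nu_2117 = 8.05e-4,
    nu_alpha_M = 2.10e-2, nu_alpha_1 = 7.35e-2,
    nu_beta_M = 5.6e-9, nu_beta_r = 3.90e-8,
    nu_21 = 4.1e-5,
    n_2r = 3,
    ## cytokine decay
    delta_gamma = 29.12, delta_4 = 349.37, delta_6 = 29.11,
    delta_10 = 116.48, delta_12 = 8.33, delta_21 = 63.98,
    delta_alpha = 388.15, delta_beta = 349.37, delta_2 = 537.46,
    ## T cells
    mu_1 = 1.4, mu_2 = 1.4, mu_17 = 1.4, mu_r = 1.4,
    sigma_12 = 10.93, sigma_2 = 1.23, sigma_4 = 1.94,
    sigma_21 = 156.17, sigma_6 = 156.17,
    sigma_beta = 14.02, sigma_10 = 14.02
  )
}

.printed_saturations <- function() {
  list(
    zeta_6 = 8.00e-6, zeta_alpha = 9.75e-6, zeta_10 = 1.54e-6,
    zeta_2 = 6.86e-8, zeta_gamma = 2.58e-6, zeta_12 = 4.90e-8,
    zeta_4 = 9.70e-9, zeta_21 = 4.25e-6, zeta_beta = 6.77e-12,
    gamma_1 = 1.83e-1, gamma_2 = 5.35e-2,
    gamma_r1 = 6.06e-2, gamma_r2 = 6.06e-2, gamma_r17 = 6.06e-2,
    gamma_17 = 3.37e-1
  )
}

#' Healthy steady-state concentrations
#'
#' The published healthy equilibrium of the model: cell densities and tissue
#' cytokine concentrations in g/cm^3.
#'
#' @return Named state vector.
#' @export
healthy_state <- function() {
  as_state_vector(c(
    M1 = 2.34e-2, M2 = 2.50e-2,
    T1 = 4.58e-2, T2 = 1.34e-2, T17 = 3.37e-1, Tr = 6.06e-2,
    Igamma = 2.58e-6, I2 = 6.86e-8, I4 = 9.70e-9, I6 = 8.00e-6,
    I10 = 1.54e-6, I12 = 4.90e-8, I21 = 4.25e-6, Ialpha = 9.75e-6,
    Ibeta = 6.77e-12))
}

.KIN_NAMES <- names(.printed_kinetics())
.SAT_NAMES <- names(.printed_saturations())

#' Model parameter sets
#'
#' Construct the model's parameter object: kinetic rates (`kin`),
#' saturation/inhibition constants (`sat`), the dialect tag and the IL-10
#' production-bracket variant. The `"printed"` dialect carries the published
#' values verbatim; the published value tables are not an exact equilibrium
#' of the published healthy state (see [audit_printed_parameters()]), so
#' dynamic work defaults to the `"self_consistent"` dialect produced by
#' [calibrate_self_consistent()], in which the healthy state is an exact
#' fixed point.
#'
#' @param dialect `"self_consistent"` (default) or `"printed"`.
#' @param eq8_numerator Which cytokine drives the IL-2 receptor-occupancy
#'   bracket of the Treg IL-10 production term: `"I2"` (default; the
#'   receptor-occupancy derivation) or `"Igamma"` (the variant printed in the
#'   source equation).
#' @return An object of class `ibd_params`: a list with elements `kin`,
#'   `sat`, `dialect`, `eq8_numerator` and, for the self-consistent dialect,
#'   `steady_state`.
#' @seealso [load_parameters()], [calibrate_self_consistent()]
#' @export
#' @examples
#' p <- default_parameters("printed")
#' p$kin$sigma_beta
default_parameters <- function(dialect = c("self_consistent", "printed"),
                               eq8_numerator = c("I2", "Igamma")) {
  dialect <- match.arg(dialect)
  eq8_numerator <- match.arg(eq8_numerator)
  if (dialect == "printed") {
    new_ibd_params(.printed_kinetics(), .printed_saturations(),
                   dialect = "printed", eq8_numerator = eq8_numerator)
  } else {
    calibrate_self_consistent(eq8_numerator = eq8_numerator)
  }
}

new_ibd_params <- function(kin, sat, dialect, eq8_numerator = "I2",
                           steady_state = NULL) {
  validate_kinetics(kin)
  validate_saturations(sat)
  structure(list(kin = kin[.KIN_NAMES], sat = sat[.SAT_NAMES],
                 dialect = dialect, eq8_numerator = eq8_numerator,
                 steady_state = steady_state),
            class = "ibd_params")
}

validate_kinetics <- function(kin) {
  missing <- setdiff(.KIN_NAMES, names(kin))
  if (length(missing))
    stop("missing kinetic parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- unlist(kin[.KIN_NAMES])
  if (any(!is.finite(v)) || any(v < 0))
    stop("kinetic parameters must be finite and non-negative", call. = FALSE)
  invisible(kin)
}

validate_saturations <- function(sat) {
  missing <- setdiff(.SAT_NAMES, names(sat))
  if (length(missing))
    stop("missing saturation constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- unlist(sat[.SAT_NAMES])
  if (any(!is.finite(v)) || any(v <= 0))
    stop("saturation constants must be finite and strictly positive",
         call. = FALSE)
  invisible(sat)
}

#' @export
print.ibd_params <- function(x, ...) {
  cat("<ibd_params> dialect:", x$dialect,
      "| IL-10 bracket numerator:", x$eq8_numerator, "\n")
  cat("  ", length(x$kin), "kinetic rates,", length(x$sat),
      "saturation/inhibition constants\n")
  if (!is.null(x$steady_state))
    cat("  carries calibrated steady state (max |rhs| rel =",
        format(max(abs(model_rhs(x$steady_state, x)) /
                     pmax(x$steady_state, 1e-300)), digits = 3), ")\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Structured config I/O

#' Read or write model parameters as a YAML config
#'
#' The config file holds the kinetic rates and saturation constants under
#' `kin:` and `sat:` keys (names as in [default_parameters()]), plus
#' `dialect` and `eq8_numerator`. The packaged default config
#' (`system.file("extdata", "parameters.yaml", package = "ibdimmune")`)
#' reproduces the published value tables verbatim.
#'
#' @param path File path.
#' @param params An `ibd_params` object.
#' @return `load_parameters()` returns an `ibd_params`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
load_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kin) || is.null(cfg$sat))
    stop("parameter config must contain 'kin' and 'sat' blocks", call. = FALSE)
  ss <- if (!is.null(cfg$steady_state)) as_state_vector(unlist(cfg$steady_state))
  new_ibd_params(cfg$kin, cfg$sat,
                 dialect = cfg$dialect %||% "printed",
                 eq8_numerator = cfg$eq8_numerator %||% "I2",
                 steady_state = ss)
}

#' @rdname load_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ibd_params"))
  out <- list(dialect = params$dialect, eq8_numerator = params$eq8_numerator,
              kin = params$kin, sat = params$sat)
  if (!is.null(params$steady_state))
    out$steady_state <- as.list(params$steady_state)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------

#' Fill in dependent kinetic rates from their fixed ratios
#'
#' Several rates are defined as fixed multiples of others rather than
#' measured independently: `sigma_M10 = 10 sigma_M_alpha`,
#' `sigma_M_beta = sigma_M_gamma = sigma_M10`, `nu_gamma_1 = 5 nu_gamma_M`,
#' `nu_21 = nu_gamma_1`, `nu_4M = nu_42 / 3`, `nu_10r = 3 nu_10M`,
#' `sigma_6 = sigma_21`, and `sigma_10 = sigma_beta`.
#'
#' @param base Named list or vector holding at least the independent rates
#'   required by the ratios being derived (`sigma_M_alpha`, `nu_gamma_M`,
#'   `nu_42`, `nu_10M`, `sigma_21`, `sigma_beta`).
#' @return List with the dependent rates added (existing entries preserved).
#' @export
#' @examples
#' derive_dependent_rates(list(sigma_M_alpha = 2.4, nu_gamma_M = 8.2e-6,
#'                             nu_42 = 1.75e-4, nu_10M = 3.72e-4,
#'                             sigma_21 = 156.17, sigma_beta = 14.02))
derive_dependent_rates <- function(base) {
  base <- as.list(base)
  need <- function(nm) {
    if (is.null(base[[nm]]))
      stop("cannot derive dependent rates: independent rate '", nm,
           "' is missing", call. = FALSE)
    base[[nm]]
  }
  base$sigma_M10 <- 10 * need("sigma_M_alpha")
  base$sigma_M_beta <- base$sigma_M10
  base$sigma_M_gamma <- base$sigma_M10
  base$nu_gamma_1 <- 5 * need("nu_gamma_M")
  base$nu_21 <- base$nu_gamma_1
  base$nu_4M <- need("nu_42") / 3
  base$nu_10r <- 3 * need("nu_10M")
  base$sigma_6 <- need("sigma_21")
  base$sigma_10 <- need("sigma_beta")
  base
}
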