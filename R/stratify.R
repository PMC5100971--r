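## Patient stratification into the four Th1/Th2 phenotypes and inverse
## fitting of per-type parameter deregulations.

#' Disease-type labels
#'
#' Type 1 = Th1-high/Th2-low, Type 2 = Th1-low/Th2-high,
#' Type 3 = Th1-high/Th2-high, Type 4 = Th1-low/Th2-low, where high/low is
#' relative to the mean healthy T-bet (T1ssh) and GATA-3 (T2ssh) levels.
#'
#' @return Named character vector mapping `Type1..Type4` to descriptors.
#' @export
disease_types <- function() {
  c(Type1 = "Th1.up_Th2.down", Type2 = "Th1.down_Th2.up",
    Type3 = "Th1.up_Th2.up", Type4 = "Th1.down_Th2.down")
}

#' Classify a patient by Th1/Th2 master-regulator levels
#'
#' A patient with T-bet above the healthy mean and GATA-3 below it is
#' Type 1; below/above gives Type 2; above/above Type 3; below/below
#' Type 4. A level exactly equal to a healthy mean is unclassifiable (the
#' rule is a strict sign pattern) and raises an error.
#'
#' @param tbet,gata3 Patient mRNA levels.
#' @param healthy_ref A [healthy_reference()] panel supplying T1ssh
#'   (`Tbet`) and T2ssh (`GATA3`).
#' @return Integer type 1-4.
#' @export
#' @examples
#' ref <- healthy_reference(baseline_mrna_means())
#' classify_patient(1.5 * ref[["Tbet"]], 0.8 * ref[["GATA3"]], ref)
classify_patient <- function(tbet, gata3, healthy_ref) {
  stopifnot(inherits(healthy_ref, "ibd_healthy_ref"))
  t1h <- healthy_ref[["Tbet"]]; t2h <- healthy_ref[["GATA3"]]
  if (tbet == t1h || gata3 == t2h)
    stop("unclassifiable: level exactly equals the healthy mean",
         call. = FALSE)
  if (tbet > t1h && gata3 < t2h) return(1L)
  if (tbet < t1h && gata3 > t2h) return(2L)
  if (tbet > t1h && gata3 > t2h) return(3L)
  4L
}

#' Classify every patient in a cohort
#'
#' @param cohort An `ibd_cohort`.
#' @param healthy_ref Reference panel; defaults to the cohort's empirical
#'   healthy means.
#' @return The cohort with an added integer column `assigned_type`
#'   (`NA` for healthy controls).
#' @export
classify_cohort <- function(cohort, healthy_ref = cohort_reference(cohort)) {
  ibd <- cohort$group == "IBD"
  cohort$assigned_type <- NA_integer_
  cohort$assigned_type[ibd] <- vapply(
    which(ibd),
    function(i) classify_patient(cohort$Tbet[i], cohort$GATA3[i], healthy_ref),
    integer(1L))
  cohort
}

## ---------------------------------------------------------------------------
## Parameter variations

.VARIED <- c("nu_gamma_1", "nu_alpha_1", "nu_beta_r", "nu_10r",
             "sigma_12", "sigma_4", "sigma_21", "sigma_6",
             "sigma_beta", "sigma_10")

#' Published per-type parameter variations
#'
#' Fractional changes of the ten varied production/activation rates in each
#' disease type, as obtained from the steady-state inverse fit of the
#' observed fold changes. The IL-21/IL-6 and TGF-beta/IL-10 signalling
#' pairs are tied; the Treg production pair (`nu_beta_r`, `nu_10r`) carries
#' identical values in every type.
#'
#' @return Data frame, rows = `Type1..Type4`, columns = the ten rates.
#' @export
table_parameter_variations <- function() {
  data.frame(
    nu_gamma_1 = c(-0.996, -0.90, 1.94, -0.92),
    nu_alpha_1 = c(-0.50, 0.04, -0.29, 0.11),
    nu_beta_r  = c(0.35, -0.10, -0.30, 0.32),
    nu_10r     = c(0.35, -0.10, -0.30, 0.32),
    sigma_12   = c(2.98, 0.81, 2.55, 0.05),
    sigma_4    = c(-0.32, 0.25, 1.22, -0.48),
    sigma_21   = c(0.49, -0.13, 2.98, -0.28),
    sigma_6    = c(0.49, -0.13, 2.98, -0.28),
    sigma_beta = c(-0.50, 0.00, 0.17, -0.18),
    sigma_10   = c(-0.50, 0.00, 0.17, -0.18),
    row.names = paste0("Type", 1:4))
}

#' Apply fractional parameter variations
#'
#' Multiplies each varied rate by `1 + change`. Ties (`sigma_6 = sigma_21`,
#' `sigma_10 = sigma_beta`) are propagated: specifying either member of a
#' pair applies the change to both (specifying both with different values
#' is an error).
#'
#' @param params An `ibd_params`.
#' @param variation Named numeric vector of fractional changes over (a
#'   subset of) `nu_gamma_1, nu_alpha_1, nu_beta_r, nu_10r, sigma_12,
#'   sigma_4, sigma_21, sigma_6, sigma_beta, sigma_10`. Changes must be
#'   > -1.
#' @return New `ibd_params` with the variation applied (the carried steady
#'   state, if any, is dropped: it no longer applies).
#' @export
#' @examples
#' p <- default_parameters()
#' p2 <- apply_variation(p, c(sigma_12 = 2.98))
#' p2$kin$sigma_12 / p$kin$sigma_12  # 3.98
apply_variation <- function(params, variation) {
  stopifnot(inherits(params, "ibd_params"))
  v <- unlist(variation)
  bad <- setdiff(names(v), .VARIED)
  if (length(bad))
    stop("unknown varied parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(v <= -1))
    stop("fractional change must be > -100%", call. = FALSE)
  for (pair in list(c("sigma_21", "sigma_6"), c("sigma_beta", "sigma_10"))) {
    hit <- intersect(names(v), pair)
    if (length(hit) == 2L && v[[pair[1L]]] != v[[pair[2L]]])
      stop("tied parameters ", paste(pair, collapse = "/"),
           " must carry identical changes", call. = FALSE)
    if (length(hit) == 1L) v[setdiff(pair, hit)] <- v[[hit]]
  }
  kin <- params$kin
  for (nm in names(v)) kin[[nm]] <- kin[[nm]] * (1 + v[[nm]])
  new_ibd_params(kin, params$sat, dialect = params$dialect,
                 eq8_numerator = params$eq8_numerator, steady_state = NULL)
}

## observable -> model-state map used by fold-change prediction
.FOLD_OBS <- c(IL6 = "I6", IL10 = "I10", TNFa = "Ialpha",
               Tbet = "T1", GATA3 = "T2", RORgt = "T17", Foxp3 = "Tr")
.FOLD_PRED <- c(TGFb = "Ibeta", IFNg = "Igamma")

#' Predict observable fold changes for a parameter variation
#'
#' Applies the variation to the healthy baseline, finds the new steady
#' state (integration plus Newton polish) and returns the fractional
#' changes of the seven measured observables - master-regulator mRNA folds
#' equal T-cell density folds because the proportionality factor lambda_T
#' cancels - plus the model-predicted TGF-beta and IFN-gamma folds.
#'
#' @param variation Named fractional changes (see [apply_variation()]).
#' @param baseline Healthy `ibd_params` carrying its steady state
#'   (default: the self-consistent calibration).
#' @return Named vector of fractional changes over
#'   `IL6, IL10, TNFa, Tbet, GATA3, RORgt, Foxp3, TGFb, IFNg`, with the
#'   diseased steady state attached as attribute `steady_state`.
#' @export
predict_fold_changes <- function(variation, baseline = default_parameters()) {
  stopifnot(inherits(baseline, "ibd_params"))
  hs <- baseline$steady_state %||% healthy_state()
  p2 <- apply_variation(baseline, variation)
  ss <- find_steady_state(p2, hs)
  keys <- c(.FOLD_OBS, .FOLD_PRED)
  fc <- ss[keys] / hs[keys] - 1
  names(fc) <- names(keys)
  attr(fc, "steady_state") <- ss
  fc
}

#' Fit per-type parameter variations to observed fold changes
#'
#' Inverse problem behind the per-type deregulation table: find fractional
#' changes of the varied rates whose predicted steady-state fold changes
#' match the seven observed targets, by least squares on fractional changes
#' (relative errors, weights `1/(1+|target|)`). The forward map requires an
#' equilibrium solve per evaluation; minimisation uses bounded
#' Levenberg-Marquardt with a finite-difference Jacobian, restarted from
#' `restarts` seeded points (first restart at zero variation).
#'
#' With `tie_treg_production = TRUE` (default) the Treg production pair
#' `nu_beta_r`/`nu_10r` moves as one, giving 7 free changes for 7 targets -
#' an identifiable system - and matching the published table, which carries
#' identical values for the pair in every type. Untied, the system has 8
#' free changes and is generically underdetermined.
#'
#' @param targets Named fractional changes for
#'   `IL6, IL10, TNFa, Tbet, GATA3, RORgt, Foxp3`, each in (-1, 10).
#' @param baseline Healthy `ibd_params` with steady state.
#' @param seed Seed governing the restart points.
#' @param restarts Number of restarts.
#' @param tie_treg_production Tie `nu_beta_r = nu_10r`.
#' @param lower,upper Box bounds on each fractional change.
#' @param loss_warn Final loss above which the result is flagged
#'   (`warning` attribute) as a poor fit.
#' @return Named vector of fitted fractional changes over all ten varied
#'   rates (ties expanded), with attributes `loss` (final sum of squares),
#'   `predicted` (fold changes at the fit) and `warning`.
#' @export
fit_type_parameters <- function(targets, baseline = default_parameters(),
                                seed = 1L, restarts = 4L,
                                tie_treg_production = TRUE,
                                lower = -0.999, upper = 5,
                                loss_warn = 1e-3) {
  tnames <- names(.FOLD_OBS)
  targets <- unlist(targets)[tnames]
  if (any(is.na(targets)))
    stop("targets must cover ", paste(tnames, collapse = ", "), call. = FALSE)
  if (any(targets <= -1 | targets >= 10))
    stop("targets must lie in (-1, 10)", call. = FALSE)
  free <- if (tie_treg_production)
    c("nu_gamma_1", "nu_alpha_1", "nu_beta_r", "sigma_12", "sigma_4",
      "sigma_21", "sigma_beta")
  else
    c("nu_gamma_1", "nu_alpha_1", "nu_beta_r", "nu_10r", "sigma_12",
      "sigma_4", "sigma_21", "sigma_beta")
  expand <- function(d) {
    v <- stats::setNames(d, free)
    if (tie_treg_production) v["nu_10r"] <- v[["nu_beta_r"]]
    v
  }
  wt <- 1 / (1 + abs(targets))
  residual <- function(d) {
    fc <- tryCatch(predict_fold_changes(expand(d), baseline),
                   error = function(e) NULL)
    if (is.null(fc)) return(rep(10, length(tnames)))
    (fc[tnames] - targets) * wt
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    d0 <- if (r == 1L) rep(0, length(free))
          else pmin(pmax(stats::rnorm(length(free), 0, 0.4), lower + 0.1),
                    upper - 2)
    fit <- tryCatch(
      minpack.lm::nls.lm(d0, lower = rep(lower, length(free)),
                         upper = rep(upper, length(free)), fn = residual,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100L, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-12) break
  }
  if (is.null(best))
    stop("fit_type_parameters: all restarts failed", call. = FALSE)
  v <- expand(best$par)
  full <- stats::setNames(numeric(length(.VARIED)), .VARIED)
  full[names(v)] <- v
  full["sigma_6"] <- full[["sigma_21"]]
  full["sigma_10"] <- full[["sigma_beta"]]
  pred <- predict_fold_changes(full, baseline)
  structure(full, loss = best$deviance, predicted = pred,
            warning = if (best$deviance > loss_warn)
              "final loss above threshold; targets may be unreachable")
}
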