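## Synthetic patient-cohort generator.
##
## The study's mucosal biopsy mRNA data are not deposited; only group-mean
## fold changes per disease type survive in print. This module generates
## healthy-control and patient mRNA panels with that group structure so the
## downstream stages (anchoring, classification, inverse fitting) are
## testable end to end. Noise is multiplicative log-normal: expression
## panels are right-skewed and strictly positive, and the log-normal is
## parameterised mean-correctly (E[X] equals the group mean exactly).

.OBSERVABLES <- c("IL6", "IL10", "TNFa", "Tbet", "GATA3", "RORgt", "Foxp3")

#' Baseline healthy mRNA means used by the generator
#'
#' Arbitrary positive mRNA-count levels chosen so that the lambda_c / IL-6
#' anchoring reproduces the published healthy tissue concentrations exactly
#' (lambda_c = 1e-8 g/cm^3 per count, lambda_T = 1e-4), i.e. the master
#' regulator means are proportional to the published T-cell densities.
#'
#' @return Named vector over the seven observables.
#' @export
baseline_mrna_means <- function() {
  c(IL6 = 800, IL10 = 154, TNFa = 975,
    Tbet = 458, GATA3 = 134, RORgt = 3370, Foxp3 = 606)
}

#' Observed per-type fold changes of the seven observables
#'
#' The group-mean fractional deviations of the measured panel from healthy
#' controls for the four Th1/Th2 disease types, together with the
#' model-predicted TGF-beta and IFN-gamma columns.
#'
#' @return Data frame, rows = Type1..Type4, columns = the seven measured
#'   observables plus `TGFb` and `IFNg` (fractions, e.g. -0.93 = -93%).
#' @export
table_fold_changes <- function() {
  out <- data.frame(
    IL6   = c(-0.93, -0.74,  0.35, -0.83),
    IL10  = c(-0.51, -0.15,  0.44, -0.34),
    TNFa  = c(-0.31, -0.31,  0.47, -0.45),
    Tbet  = c( 0.50, -0.29,  1.10, -0.46),
    GATA3 = c(-0.22,  0.50,  0.75, -0.40),
    RORgt = c( 0.50, -0.27, -0.14, -0.11),
    Foxp3 = c(-0.71,  0.01,  0.70, -0.42),
    TGFb  = c(-0.56, -0.06,  0.19, -0.20),
    IFNg  = c(-0.99, -0.92,  4.81, -0.95),
    row.names = paste0("Type", 1:4))
  out
}

#' Cohort specification
#'
#' @param counts Patients per disease type (Type1..Type4).
#' @param n_healthy Number of healthy-control records.
#' @param fold_changes Per-type mean fold changes of the seven observables;
#'   defaults to the observed group means ([table_fold_changes()]).
#' @param baseline Healthy mRNA means ([baseline_mrna_means()]).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (0 = deterministic draws at the group means).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param enforce_types Redraw any patient record whose T-bet/GATA3 levels
#'   violate its own type's classification signs relative to the baseline
#'   means (guarantees label consistency; slightly truncates the marginal
#'   distributions).
#' @return Object of class `ibd_cohort_spec`.
#' @export
cohort_spec <- function(counts = c(7L, 18L, 17L, 16L), n_healthy = 20L,
                        fold_changes = table_fold_changes()[.OBSERVABLES],
                        baseline = baseline_mrna_means(),
                        noise_cv = 0.15, seed = 1L, enforce_types = TRUE) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || any(counts < 0L))
    stop("counts must be four non-negative integers", call. = FALSE)
  if (n_healthy < 0L) stop("n_healthy must be >= 0", call. = FALSE)
  fc <- as.matrix(fold_changes)[, .OBSERVABLES, drop = FALSE]
  if (nrow(fc) != 4L) stop("fold_changes needs one row per type", call. = FALSE)
  if (any(fc <= -1)) stop("fold changes must exceed -100%", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(counts = counts, n_healthy = as.integer(n_healthy),
                 fold_changes = fc, baseline = baseline[.OBSERVABLES],
                 noise_cv = noise_cv, seed = as.integer(seed),
                 enforce_types = enforce_types),
            class = "ibd_cohort_spec")
}

## mean-correct log-normal draw: E[X] = m for every noise_cv
.rlnorm_mean <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

#' Generate a synthetic cohort
#'
#' Draws healthy-control records log-normally around the baseline means and
#' patient records around `baseline * (1 + fold_change(type))`. Each patient
#' record carries its true disease type; under `enforce_types` a record
#' whose T-bet/GATA3 pattern contradicts its own type (relative to the
#' baseline means) is redrawn and the redraw count recorded in the
#' manifest.
#'
#' @param spec An [cohort_spec()] object.
#' @return Data frame of class `ibd_cohort`, one row per subject, columns
#'   `subject_id`, `group` (`healthy`/`IBD`), `type` (1-4, `NA` for
#'   healthy) and the seven observables. The generation manifest (spec,
#'   seed, baselines, redraw count) is attached as attribute `manifest`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(noise_cv = 0, seed = 1))
#' table(cohort$type, useNA = "ifany")
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ibd_cohort_spec"))
  set.seed(spec$seed)
  bl <- spec$baseline
  cv <- spec$noise_cv

  draw_record <- function(means) {
    vapply(.OBSERVABLES, function(o) .rlnorm_mean(1L, means[[o]], cv),
           numeric(1L))
  }
  rows <- list(); redraws <- 0L
  for (i in seq_len(spec$n_healthy))
    rows[[length(rows) + 1L]] <- c(type = NA_real_, draw_record(bl))

  ## classification sign each type must satisfy: sign(Tbet - baseline),
  ## sign(GATA3 - baseline)
  sign_tbet <- c(1, -1, 1, -1); sign_gata <- c(-1, 1, 1, -1)
  for (ty in 1:4) {
    means <- bl * (1 + spec$fold_changes[ty, ])
    n_drawn <- 0L
    for (i in seq_len(spec$counts[ty])) {
      repeat {
        rec <- draw_record(means)
        n_drawn <- n_drawn + 1L
        ok <- !spec$enforce_types ||
          (sign(rec[["Tbet"]] - bl[["Tbet"]]) == sign_tbet[ty] &&
             sign(rec[["GATA3"]] - bl[["GATA3"]]) == sign_gata[ty])
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 0.5 * (sum(spec$counts) + redraws) && redraws > 50L)
          stop("generation error: noise scale forces more than half of all ",
               "draws to be redrawn; reduce noise_cv", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- c(type = ty, rec)
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(nrow(m))),
    group = c(rep("healthy", spec$n_healthy), rep("IBD", sum(spec$counts))),
    type = as.integer(m[, "type"]),
    m[, .OBSERVABLES, drop = FALSE],
    row.names = NULL)
  structure(out, class = c("ibd_cohort", "data.frame"),
            manifest = list(counts = spec$counts, n_healthy = spec$n_healthy,
                            fold_changes = spec$fold_changes,
                            baseline = bl, noise_cv = cv, seed = spec$seed,
                            enforce_types = spec$enforce_types,
                            redraws = redraws))
}

#' Write / read a cohort as tidy CSV plus JSON manifest
#'
#' `write_cohort()` stores the records as `cohort.csv` and the generation
#' manifest as `manifest.json` under `dir`; `read_cohort()` round-trips
#' them (values restored bit-exactly via full-precision formatting).
#'
#' @param cohort An `ibd_cohort` data frame.
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` the
#'   cohort.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ibd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(cohort)
  for (o in .OBSERVABLES) df[[o]] <- sprintf("%.17g", df[[o]])
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  man <- attr(cohort, "manifest")
  man$baseline <- as.list(man$baseline)   # keep names through JSON
  man$fold_changes <- as.data.frame(man$fold_changes)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  df <- utils::read.csv(file.path(dir, "cohort.csv"),
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       type = "integer"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$fold_changes <- as.matrix(man$fold_changes)
  man$baseline <- unlist(man$baseline)
  structure(df, class = c("ibd_cohort", "data.frame"), manifest = man)
}

#' Healthy reference panel from a cohort
#'
#' Column means of the healthy-control records, as a
#' [healthy_reference()] object. With `from_manifest = TRUE` the
#' generator's exact baseline means are used instead of the (noisy)
#' empirical means.
#'
#' @param cohort An `ibd_cohort`.
#' @param from_manifest Use the stored generator baselines.
#' @return `ibd_healthy_ref`.
#' @export
cohort_reference <- function(cohort, from_manifest = FALSE) {
  if (from_manifest) {
    man <- attr(cohort, "manifest")
    if (is.null(man)) stop("cohort carries no manifest", call. = FALSE)
    return(healthy_reference(man$baseline))
  }
  h <- cohort[cohort$group == "healthy", .OBSERVABLES, drop = FALSE]
  if (!nrow(h)) stop("cohort contains no healthy controls", call. = FALSE)
  healthy_reference(colMeans(h))
}
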