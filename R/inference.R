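# Translocation inference: fraction definitions, the 1-D translocation-rate
# fit, the biliary-excretion adjustment factor, bound scenarios from
# biodistribution records, and prediction of full biodistributions from an
# in vitro fraction.

# compartments counted as "secondary organs" evidence of translocation: the
# lung (both pools), the whole GIT (tissue + lumen) and feces are excluded
# because in vivo the gavage-vs-biliary origin of GIT/fecal material is
# ambiguous; blood and urine are included.
SECONDARY_EXCLUDE <- c("lung_deposition", "lung_tissue", "GIT_tissue",
                       "GIT_lumen", "feces")

new_translocation_fraction <- function(time, fraction, sd = NA_real_,
                                       basis = c("total_flux",
                                                 "secondary_organs"),
                                       replicates = NULL) {
  basis <- match.arg(basis)
  stopifnot(fraction >= -1e-12, fraction <= 1 + 1e-9)
  structure(list(time = time, fraction = min(max(fraction, 0), 1), sd = sd,
                 basis = basis, replicates = replicates),
            class = "translocation_fraction")
}

#' Construct a translocation fraction observation
#'
#' @param time Time post-exposure in h.
#' @param fraction Dimensionless fraction in `[0, 1]`.
#' @param sd Replicate standard deviation (dimensionless, `NA` if unknown).
#' @param basis `"secondary_organs"` (fraction reconstructed from burdens in
#'   blood, secondary organs and urine, the in vivo observable) or
#'   `"total_flux"` (total material that crossed the lung epithelium, the in
#'   vitro observable).
#' @return An object of class `translocation_fraction`.
#' @export
translocation_fraction <- function(time, fraction, sd = NA_real_,
                                   basis = c("total_flux",
                                             "secondary_organs")) {
  new_translocation_fraction(time, fraction, sd, basis)
}

#' @export
print.translocation_fraction <- function(x, ...) {
  cat(sprintf("<translocation_fraction> %.4g%% at %g h (%s)%s\n",
              100 * x$fraction, x$time, x$basis,
              if (is.finite(x$sd)) sprintf(" +/- %.2g%%", 100 * x$sd) else ""))
  invisible(x)
}

#' Secondary-organ-based translocation fraction of a trajectory
#'
#' The fraction of the dose found outside the lung, the GIT (tissue and
#' lumen) and feces -- i.e. in blood, liver, spleen, kidneys, heart, brain,
#' carcass and urine. This mirrors how animal studies compute translocation
#' when biliary and mucociliary contributions to the gut cannot be told
#' apart, and therefore *under*-states total translocation whenever biliary
#' or fecal excretion of absorbed material occurred.
#'
#' Note that with this basis the measured fraction is below the total
#' translocated fraction even without excretion, because translocated
#' material recirculating into the (excluded) lung tissue and GIT tissue is
#' not counted; `exclude` makes the basis configurable against a specific
#' literature source's bookkeeping.
#'
#' @param traj A `pbpk_trajectory`.
#' @param t Time in h within the trajectory span.
#' @param exclude Compartments not counted as translocation evidence.
#' @return A `translocation_fraction` with basis `"secondary_organs"`.
#' @export
measured_fraction <- function(traj, t, exclude = SECONDARY_EXCLUDE) {
  a <- interp_amounts(traj, t)
  keep <- setdiff(traj$compartments, exclude)
  new_translocation_fraction(t, sum(a[keep]) / traj$dose,
                             basis = "secondary_organs")
}

#' Total translocation fraction of a trajectory
#'
#' Cumulative lung-to-blood flux divided by the deposited dose: the total
#' fraction of deposited material that has crossed the epithelial barrier by
#' time `t`, regardless of where it subsequently went.
#'
#' @inheritParams measured_fraction
#' @return A `translocation_fraction` with basis `"total_flux"`.
#' @export
total_fraction <- function(traj, t) {
  new_translocation_fraction(t, interp_flux(traj, t) / traj$dose,
                             basis = "total_flux")
}

model_fraction <- function(system, exposure, t, basis) {
  times <- sort(unique(c(0, if (exposure$duration > 0) exposure$duration, t)))
  if (length(times) < 2) times <- c(0, t)
  traj <- simulate_pbpk(system, exposure, times)
  if (basis == "total_flux") total_fraction(traj, t)$fraction
  else measured_fraction(traj, t)$fraction
}

#' Fit the lung-to-blood translocation rate to a target fraction
#'
#' One-dimensional bisection on `k_ab`. At fixed time the model fraction
#' (either basis) is strictly increasing in `k_ab` with everything else
#' fixed, so bisection is globally convergent. Iterates until the model
#' fraction matches the target within `tol`.
#'
#' @param system A [build_system()] result used as template (its `k_ab` is
#'   replaced during the search).
#' @param target A [translocation_fraction()]; its `basis` selects the
#'   objective and its `time` the evaluation point.
#' @param exposure The [exposure_event()] under which the target was
#'   observed.
#' @param bracket Search interval for `k_ab` in 1/h (default `c(0, 10)`).
#' @param tol Absolute tolerance on the fraction (default 1e-6).
#' @param max_iter Iteration cap.
#' @return An object of class `fit_result`: `k_ab_fitted`,
#'   `objective_residual`, `converged`, `iterations`.
#' @export
fit_translocation_rate <- function(system, target, exposure,
                                   bracket = c(0, 10), tol = 1e-6,
                                   max_iter = 200L) {
  stopifnot(inherits(target, "translocation_fraction"),
            target$fraction >= 0, target$fraction < 1)
  f_of <- function(k) {
    model_fraction(set_kab(system, k), exposure, target$time, target$basis)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f_of(lo) - target$fraction
  fhi <- f_of(hi) - target$fraction
  iters <- 2L
  if (flo > tol || fhi < -tol) {
    return(structure(list(k_ab_fitted = NA_real_,
                          objective_residual = min(abs(flo), abs(fhi)),
                          converged = FALSE, iterations = iters,
                          message = "target unreachable within bracket"),
                     class = "fit_result"))
  }
  if (abs(flo) <= tol) {
    return(structure(list(k_ab_fitted = lo, objective_residual = abs(flo),
                          converged = TRUE, iterations = iters),
                     class = "fit_result"))
  }
  k <- NA_real_; fk <- NA_real_
  while (iters < max_iter) {
    k <- (lo + hi) / 2
    fk <- f_of(k) - target$fraction
    iters <- iters + 1L
    if (abs(fk) <= tol) break
    if (fk < 0) lo <- k else hi <- k
  }
  structure(list(k_ab_fitted = k, objective_residual = abs(fk),
                 converged = abs(fk) <= tol, iterations = iters),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> k_ab = %.6g 1/h, residual %.3g, %s (%d iterations)\n",
              x$k_ab_fitted, x$objective_residual,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Biliary-excretion adjustment factor
#'
#' In vivo, translocation is measured from secondary-organ burdens; material
#' that translocated but was already excreted via bile into the gut (or via
#' urine, if urine is not collected) is missed. This operation fits `k_ab`
#' so that the model's secondary-organ fraction matches the measurement,
#' then reports the model's total translocated fraction at the same time and
#' the ratio `factor = total / measured`. With non-negative excretion rates
#' the factor is always `>= 1`, and equals 1 exactly when no excretory
#' pathway is active.
#'
#' @param system Template [build_system()] result.
#' @param measured A `translocation_fraction` with basis
#'   `"secondary_organs"` and `fraction > 0`.
#' @param exposure The [exposure_event()] of the measurement (default: a
#'   100-unit instillation bolus).
#' @param ... Passed to [fit_translocation_rate()].
#' @return List with `k_ab_fitted`, `fit` (the full `fit_result`), `total`
#'   (a `translocation_fraction`, basis total_flux) and `factor`.
#' @export
adjustment_factor <- function(system, measured,
                              exposure = exposure_event("instillation_bolus"),
                              ...) {
  stopifnot(inherits(measured, "translocation_fraction"))
  if (measured$basis != "secondary_organs") {
    stop("adjustment_factor requires a secondary_organs-basis measurement")
  }
  if (measured$fraction <= 0) {
    stop("adjustment factor undefined for a zero measured fraction")
  }
  fit <- fit_translocation_rate(system, measured, exposure, ...)
  if (!fit$converged) stop("translocation-rate fit did not converge")
  sys <- set_kab(system, fit$k_ab_fitted)
  times <- sort(unique(c(0, if (exposure$duration > 0) exposure$duration,
                         measured$time)))
  traj <- simulate_pbpk(sys, exposure, times)
  tot <- total_fraction(traj, measured$time)
  list(k_ab_fitted = fit$k_ab_fitted, fit = fit, total = tot,
       factor = tot$fraction / measured$fraction)
}

#' Bound scenarios for translocation from a biodistribution record
#'
#' Material recovered from the GIT and feces after lung exposure is
#' ambiguous: it may have been cleared mucociliarly (never translocated) or
#' excreted via bile after uptake. The lower bound attributes all of it to
#' mucociliary clearance; the upper bound attributes all of it to biliary
#' excretion of translocated material.
#'
#' @param record A [biodistribution_record()]; burdens must include `lung`,
#'   `GIT` and `feces` entries.
#' @return List of two `translocation_fraction`s, `lower` and `upper`.
#' @export
translocation_bounds <- function(record) {
  stopifnot(inherits(record, "biodistribution_record"))
  need <- c("lung", "GIT", "feces")
  missing <- setdiff(need, names(record$burdens))
  if (length(missing)) {
    stop("biodistribution record lacks required organs: ",
         paste(missing, collapse = ", "))
  }
  rest <- setdiff(names(record$burdens), need)
  lower <- sum(record$burdens[rest]) / 100
  upper <- lower + (record$burdens[["GIT"]] + record$burdens[["feces"]]) / 100
  list(lower = new_translocation_fraction(record$time, lower,
                                          basis = "secondary_organs"),
       upper = new_translocation_fraction(record$time, min(upper, 1),
                                          basis = "total_flux"))
}

#' Construct a biodistribution record
#'
#' Organ burdens in percent of dose at one time point, the shape of in vivo
#' literature data. Burden names should use `lung` (whole measurable lung),
#' `GIT` (tissue plus contents) and `feces` alongside any secondary organs,
#' `blood` and `urine`.
#'
#' @param time Time post-exposure, h.
#' @param burdens Named numeric vector, percent of dose, all `>= 0`.
#' @param slack Permitted measurement excess above 100\% (default 10).
#' @return An object of class `biodistribution_record`.
#' @export
biodistribution_record <- function(time, burdens, slack = 10) {
  stopifnot(is.numeric(burdens), !is.null(names(burdens)), all(burdens >= 0))
  if (sum(burdens) > 100 + slack) {
    stop("organ burdens sum to more than 100% + slack")
  }
  structure(list(time = time, burdens = burdens),
            class = "biodistribution_record")
}

#' Read / write biodistribution records
#'
#' CSV format: a comment header line `# time_h: <t>` followed by
#' `organ,pct_dose` rows.
#'
#' @param file Path.
#' @return For `read_biodistribution`, a `biodistribution_record`.
#' @export
read_biodistribution <- function(file) {
  first <- readLines(file, n = 1)
  m <- regmatches(first, regexec("^#\\s*time_h:\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("missing '# time_h: <t>' header in ", file)
  tab <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  biodistribution_record(as.numeric(m[2]),
                         setNames(tab$pct_dose, tab$organ))
}

#' @rdname read_biodistribution
#' @param record A `biodistribution_record` to write.
#' @export
write_biodistribution <- function(record, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_h: %g", record$time), con)
  write.csv(data.frame(organ = names(record$burdens),
                       pct_dose = as.numeric(record$burdens)),
            con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Scale translocation fractions by a common adjustment factor
#'
#' Used to propagate the biliary-excretion adjustment determined for one
#' particle size to the measured fractions of other sizes. Products above 1
#' are clamped to 1 and flagged.
#'
#' @param fractions List of `translocation_fraction`s.
#' @param factor Multiplier `>= 1`.
#' @return List of scaled `translocation_fraction`s; each carries a logical
#'   `clamped` element.
#' @export
scale_fractions <- function(fractions, factor) {
  stopifnot(is.numeric(factor), factor >= 1)
  lapply(fractions, function(fr) {
    stopifnot(inherits(fr, "translocation_fraction"))
    val <- fr$fraction * factor
    out <- new_translocation_fraction(
      fr$time, min(val, 1),
      sd = if (is.finite(fr$sd)) fr$sd * factor else fr$sd,
      basis = fr$basis)
    out$clamped <- val > 1
    out
  })
}

#' Predict a full biodistribution from an in vitro translocation fraction
#'
#' The second step of the two-step in vitro / in silico chain: the transwell
#' fraction is a *total* translocation measurement (everything in the
#' basolateral medium crossed the barrier), so `k_ab` is fitted on the
#' total-flux basis at the fraction's time point and the whole-body
#' distribution is then simulated.
#'
#' @param system Template [build_system()] result.
#' @param in_vitro_fraction A `translocation_fraction` with basis
#'   `"total_flux"`.
#' @param exposure An [exposure_event()].
#' @param times Output time grid.
#' @param ... Passed to [fit_translocation_rate()].
#' @return A `pbpk_trajectory`; the fitted rate is attached as attribute
#'   `"fit"`.
#' @export
predict_biodistribution <- function(system, in_vitro_fraction, exposure,
                                    times, ...) {
  stopifnot(inherits(in_vitro_fraction, "translocation_fraction"))
  if (in_vitro_fraction$basis != "total_flux") {
    stop("predict_biodistribution expects a total_flux-basis fraction")
  }
  if (in_vitro_fraction$fraction == 0) {
    sys <- set_kab(system, 0)
    traj <- simulate_pbpk(sys, exposure, times)
    attr(traj, "fit") <- structure(list(k_ab_fitted = 0,
                                        objective_residual = 0,
                                        converged = TRUE, iterations = 0L),
                                   class = "fit_result")
    return(traj)
  }
  fit <- fit_translocation_rate(system, in_vitro_fraction, exposure, ...)
  if (!fit$converged) stop("translocation-rate fit did not converge")
  traj <- simulate_pbpk(set_kab(system, fit$k_ab_fitted), exposure,
                        sort(unique(c(times, in_vitro_fraction$time))))
  keep <- traj$times %in% times
  traj$amounts <- traj$amounts[keep, , drop = FALSE]
  traj$cumulative_lung_to_blood_flux <-
    traj$cumulative_lung_to_blood_flux[keep]
  traj$times <- traj$times[keep]
  attr(traj, "fit") <- fit
  traj
}
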