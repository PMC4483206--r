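# Monte Carlo propagation of log-normal parameter uncertainty. Each
# parameter p is drawn log-normally with median equal to its nominal value
# and the geometric SD carried in the parameter tables' `gsd` column.
# Iterations use independent RNG streams derived from (seed, iteration) so
# results do not depend on execution order.

#' Monte Carlo settings
#'
#' @param iterations Number of iterations (default 1000).
#' @param seed Integer RNG seed.
#' @param percentiles Probabilities of the reported pointwise percentile
#'   curves (default 2.5/50/97.5\%, a conventional 95\% interval).
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(iterations = 1000L, seed = 1L,
                             percentiles = c(0.025, 0.5, 0.975)) {
  stopifnot(iterations >= 1, all(percentiles > 0 & percentiles < 1),
            !is.unsorted(percentiles))
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 percentiles = percentiles),
            class = "uncertainty_spec")
}

iteration_seed <- function(seed, iteration) {
  (abs(seed) %% 2^20L) * 2048L + (iteration %% 2048L)
}

draw_lognormal <- function(nominal, gsd) {
  if (is.null(gsd) || !is.finite(gsd) || gsd <= 1 || nominal == 0) {
    return(nominal)  # gsd 1 (or an unperturbable zero) -> exactly nominal
  }
  nominal * exp(rnorm(1L) * log(gsd))
}

#' Draw one perturbed parameter set
#'
#' Deterministic given `(spec$seed, iteration)`. Every physiological and
#' kinetic parameter with `gsd > 1` is drawn log-normally with median at its
#' nominal value; organ blood flows are rescaled proportionally whenever
#' their sampled sum exceeds the sampled cardiac output, so the perturbed
#' physiology always validates.
#'
#' @param phys Nominal [load_physiology()] result.
#' @param rates Nominal [kinetic_rates()] object.
#' @param spec An [uncertainty_spec()].
#' @param iteration Iteration index (1-based).
#' @return List with perturbed `phys` and `rates`.
#' @export
sample_parameters <- function(phys, rates, spec, iteration) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(iteration_seed(spec$seed, iteration))

  p <- phys
  p$blood_volume <- draw_lognormal(phys$blood_volume,
                                   phys$gsd[["blood_volume"]])
  p$cardiac_output <- draw_lognormal(phys$cardiac_output,
                                     phys$gsd[["cardiac_output"]])
  p$organs$blood_flow <- vapply(seq_len(nrow(phys$organs)), function(i) {
    draw_lognormal(phys$organs$blood_flow[i],
                   phys$gsd[[paste0(phys$organs$organ[i], ".blood_flow")]])
  }, numeric(1))
  tot <- sum(p$organs$blood_flow)
  if (tot > p$cardiac_output) {
    p$organs$blood_flow <- p$organs$blood_flow * p$cardiac_output / tot
  }

  r <- rates
  for (nm in RATE_NAMES) {
    g <- if (!is.null(rates$gsd) && nm %in% names(rates$gsd)) {
      rates$gsd[[nm]]
    }
    r[[nm]] <- draw_lognormal(rates[[nm]], g)
  }
  list(phys = p, rates = r)
}

extract_output <- function(traj, output) {
  if (is.function(output)) return(output(traj))
  if (output == "total_fraction") {
    traj$cumulative_lung_to_blood_flux / traj$dose
  } else if (output == "measured_fraction") {
    keep <- setdiff(traj$compartments, SECONDARY_EXCLUDE)
    rowSums(traj$amounts[, keep, drop = FALSE]) / traj$dose
  } else if (startsWith(output, "burden:")) {
    comp <- sub("^burden:", "", output)
    if (comp == "lung") {
      100 * (traj$amounts[, "lung_deposition"] +
               traj$amounts[, "lung_tissue"]) / traj$dose
    } else {
      100 * traj$amounts[, comp] / traj$dose
    }
  } else {
    stop("unknown output selector: ", output)
  }
}

#' Monte Carlo uncertainty bands for a trajectory-derived output
#'
#' Per iteration, a perturbed parameter set is drawn with
#' [sample_parameters()], the system rebuilt and simulated, and the selected
#' output extracted on the common time grid; pointwise percentiles are then
#' reported. Iterations whose solver fails are recorded and excluded; more
#' than 1\% failures is an error. Reproducible for a fixed seed.
#'
#' @param phys,rates Nominal parameter objects.
#' @param exposure An [exposure_event()].
#' @param times Output time grid.
#' @param output `"total_fraction"`, `"measured_fraction"`,
#'   `"burden:<compartment>"` (percent of dose; `burden:lung` sums both lung
#'   pools), or a function of a trajectory returning a numeric series on
#'   `times`.
#' @param spec An [uncertainty_spec()].
#' @param particle Optional [particle_spec()] forwarded to [build_system()].
#' @return An object of class `uncertainty_bands`: `times`, `quantiles`
#'   (time x percentile matrix), `nominal` (unperturbed curve), `output`,
#'   `iterations`, `failures`, `seed`.
#' @export
run_monte_carlo <- function(phys, rates, exposure, times,
                            output = "total_fraction",
                            spec = uncertainty_spec(), particle = NULL) {
  draws <- matrix(NA_real_, spec$iterations, length(times))
  failures <- 0L
  for (i in seq_len(spec$iterations)) {
    par <- sample_parameters(phys, rates, spec, i)
    res <- tryCatch({
      sys <- build_system(par$phys, par$rates, particle)
      extract_output(simulate_pbpk(sys, exposure, times), output)
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else draws[i, ] <- res
  }
  if (failures > 0.01 * spec$iterations) {
    stop(failures, " of ", spec$iterations, " Monte Carlo iterations failed")
  }
  q <- t(apply(draws, 2, quantile, probs = spec$percentiles, na.rm = TRUE,
               names = FALSE, type = 7))
  colnames(q) <- paste0("p", 100 * spec$percentiles)
  nominal <- extract_output(
    simulate_pbpk(build_system(phys, rates, particle), exposure, times),
    output)
  structure(list(times = times, quantiles = q, nominal = nominal,
                 output = if (is.function(output)) "custom" else output,
                 iterations = spec$iterations, failures = failures,
                 seed = spec$seed),
            class = "uncertainty_bands")
}

#' @export
print.uncertainty_bands <- function(x, ...) {
  cat(sprintf("<uncertainty_bands> %s, n = %d iterations (%d failed), seed %d\n",
              x$output, x$iterations, x$failures, x$seed))
  invisible(x)
}

#' Write uncertainty bands to CSV
#'
#' @param bands An `uncertainty_bands` object.
#' @param file Output path (`time_h,output,<one column per percentile>`).
#' @return `file`, invisibly.
#' @export
write_bands <- function(bands, file) {
  df <- data.frame(time_h = bands$times, output = bands$output,
                   bands$quantiles, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
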