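# Solvers for the compartmental system. Two independent paths:
#  * simulate_pbpk(): adaptive Dormand-Prince RK45 time stepping;
#  * matrix_exponential_solve(): scaling-and-squaring via Matrix::expm.
# The state vector is augmented with the cumulative lung-to-blood flux
# integral(k_ab * A_lung_deposition dt), which both paths propagate.

# Dormand-Prince RK45 tableau
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# integrate dy/dt = f(t, y) from t0 to t1 (adaptive step, FSAL not exploited)
rk45_segment <- function(f, y0, t0, t1, rtol, atol) {
  t <- t0
  y <- y0
  h <- (t1 - t0) / 10
  k <- vector("list", 7)
  while (t < t1) {
    h <- min(h, t1 - t)
    k[[1]] <- f(t, y)
    for (s in 2:7) {
      a <- if (s < 7) .dp_a[[s - 1]] else .dp_b5[1:6]
      acc <- y
      for (j in seq_along(a)) if (a[j] != 0) acc <- acc + h * a[j] * k[[j]]
      k[[s]] <- f(t + .dp_c[s] * h, acc)
    }
    y5 <- y
    for (j in 1:7) if (.dp_b5[j] != 0) y5 <- y5 + h * .dp_b5[j] * k[[j]]
    y4 <- y
    for (j in 1:7) if (.dp_b4[j] != 0) y4 <- y4 + h * .dp_b4[j] * k[[j]]
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) stop("RK45 solver produced non-finite values")
    if (err <= 1) {
      t <- t + h
      y <- y5
    }
    fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
    h <- h * min(5, max(0.2, fac))
    if (h <= .Machine$double.eps * max(1, abs(t))) {
      stop("RK45 solver step size underflow at t = ", t)
    }
  }
  y
}

exposure_source <- function(system, exposure) {
  n <- length(system$compartments)
  if (exposure$route == "instillation_bolus") {
    list(y0 = c(exposure$deposited_dose, rep(0, n - 1)),
         rate = rep(0, n), until = 0)
  } else {
    u <- rep(0, n)
    u[1] <- exposure$deposited_dose / exposure$duration
    list(y0 = rep(0, n), rate = u, until = exposure$duration)
  }
}

new_trajectory <- function(times, amounts, flux, dose, exposure, compartments) {
  colnames(amounts) <- compartments
  structure(list(times = times, amounts = amounts,
                 cumulative_lung_to_blood_flux = flux, dose = dose,
                 exposure = exposure, compartments = compartments),
            class = "pbpk_trajectory")
}

#' Simulate the biodistribution after lung deposition
#'
#' Solves `dA/dt = M A + u(t)` with `A(0) = 0` by adaptive Dormand-Prince
#' RK45 time stepping (relative tolerance `rtol`, independent of the output
#' grid). A bolus is implemented as an initial condition on the
#' lung-deposition pool; constant inhalation as a constant source into it for
#' `t <= duration`. The cumulative lung-to-blood flux
#' `integral(k_ab * A_lung_deposition dt)` is co-integrated.
#'
#' @param system A [build_system()] result.
#' @param exposure An [exposure_event()].
#' @param times Output time grid in h, starting at 0, strictly increasing.
#' @param rtol,atol Solver tolerances (defaults 1e-8 and `1e-10 * dose`).
#' @return A `pbpk_trajectory`: `times`, `amounts` (time x compartment, same
#'   unit as the dose), `cumulative_lung_to_blood_flux`, `dose`, `exposure`.
#' @export
#' @examples
#' sys <- build_system(load_physiology("rat"),
#'                     load_kinetic_rates(list(k_ab = 0.01)))
#' traj <- simulate_pbpk(sys, exposure_event("instillation_bolus", 100),
#'                       times = 0:24)
simulate_pbpk <- function(system, exposure, times, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(system, "compartment_system"),
            inherits(exposure, "exposure_event"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must start at 0 and be strictly increasing")
  }
  dose <- exposure$deposited_dose
  if (is.null(atol)) atol <- 1e-10 * max(dose, 1)
  n <- length(system$compartments)
  M <- system$M
  k_ab <- M["blood", "lung_deposition"]
  src <- exposure_source(system, exposure)

  # augmented state: compartments + cumulative lung->blood flux
  f_on <- function(t, y) {
    a <- y[1:n]
    c(as.vector(M %*% a) + src$rate, k_ab * a[1])
  }
  f_off <- function(t, y) {
    a <- y[1:n]
    c(as.vector(M %*% a), k_ab * a[1])
  }

  # break points: output times plus the end of a constant-inhalation phase
  grid <- sort(unique(c(times, if (src$until > 0) src$until)))
  y <- c(src$y0, 0)
  out <- matrix(NA_real_, length(times), n)
  flux <- numeric(length(times))
  if (times[1] == 0) {
    out[1, ] <- y[1:n]
    flux[1] <- y[n + 1]
  }
  tprev <- 0
  for (tt in grid[grid > 0]) {
    f <- if (tprev < src$until) f_on else f_off
    y <- rk45_segment(f, y, tprev, tt, rtol, atol)
    idx <- match(tt, times)
    if (!is.na(idx)) {
      out[idx, ] <- y[1:n]
      flux[idx] <- y[n + 1]
    }
    tprev <- tt
  }

  if (min(out) < -1e-7 * max(dose, 1)) {
    stop("solver produced negative amounts beyond tolerance (min = ",
         format(min(out)), ")")
  }
  new_trajectory(times, out, flux, dose, exposure, system$compartments)
}

#' Matrix-exponential reference solution for a bolus
#'
#' Independent oracle for [simulate_pbpk()]: for an instillation bolus the
#' system is linear and autonomous, so `A(t) = expm(M t) A(0)` exactly. The
#' exponential (scaling-and-squaring, `Matrix::expm`) is applied to the
#' augmented matrix that also carries the cumulative lung-to-blood flux, a
#' different code path from the RK45 time stepper.
#'
#' @param system A [build_system()] result.
#' @param bolus An [exposure_event()] with route `"instillation_bolus"`.
#' @param times Output grid, starting at 0, strictly increasing.
#' @return A `pbpk_trajectory`.
#' @export
matrix_exponential_solve <- function(system, bolus, times) {
  stopifnot(inherits(system, "compartment_system"),
            inherits(bolus, "exposure_event"))
  if (bolus$route != "instillation_bolus") {
    stop("matrix_exponential_solve supports instillation_bolus only")
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must start at 0 and be strictly increasing")
  }
  M <- system$M
  if (any(!is.finite(M))) stop("non-finite entries in the rate matrix")
  n <- length(system$compartments)
  Maug <- rbind(cbind(M, 0), 0)
  Maug[n + 1, 1] <- M["blood", "lung_deposition"]   # d flux/dt = k_ab * A_dep
  y0 <- c(bolus$deposited_dose, rep(0, n))
  out <- matrix(NA_real_, length(times), n)
  flux <- numeric(length(times))
  for (i in seq_along(times)) {
    yt <- if (times[i] == 0) y0 else {
      as.numeric(Matrix::expm(Matrix::Matrix(Maug * times[i])) %*% y0)
    }
    out[i, ] <- yt[1:n]
    flux[i] <- yt[n + 1]
  }
  new_trajectory(times, out, flux, bolus$deposited_dose, bolus,
                 system$compartments)
}

delivered_dose <- function(exposure, t) {
  if (exposure$route == "instillation_bolus") {
    rep(exposure$deposited_dose, length(t))
  } else {
    exposure$deposited_dose * pmin(t, exposure$duration) / exposure$duration
  }
}

#' Audit mass conservation of a trajectory
#'
#' Returns the maximum over the output grid of
#' `|sum(all compartments) - dose delivered by t| / total dose`. Because
#' urine and feces are explicit absorbing sinks, a correctly solved
#' trajectory conserves mass to solver tolerance.
#'
#' @param traj A `pbpk_trajectory`.
#' @param exposure The [exposure_event()] that produced it (defaults to the
#'   one stored in the trajectory).
#' @return Dimensionless worst-case relative mass-balance error.
#' @export
mass_balance_error <- function(traj, exposure = traj$exposure) {
  dose <- exposure$deposited_dose
  if (dose == 0) return(0)
  got <- rowSums(traj$amounts)
  want <- delivered_dose(exposure, traj$times)
  max(abs(got - want)) / dose
}

interp_amounts <- function(traj, t) {
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("time ", t, " outside the trajectory span")
  }
  vapply(seq_along(traj$compartments), function(j) {
    approx(traj$times, traj$amounts[, j], xout = t)$y
  }, numeric(1)) |> setNames(traj$compartments)
}

interp_flux <- function(traj, t) {
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("time ", t, " outside the trajectory span")
  }
  approx(traj$times, traj$cumulative_lung_to_blood_flux, xout = t)$y
}

#' Organ burden as percent of dose
#'
#' Linear interpolation between trajectory grid points. The name `"lung"`
#' reports the measurable lung burden, i.e. the sum of the lung-deposition
#' pool and the perfused lung tissue (in vivo the two cannot be
#' distinguished).
#'
#' @param traj A `pbpk_trajectory`.
#' @param t Query time in h, inside the trajectory span.
#' @param organs Character vector of compartment names, optionally including
#'   `"lung"`.
#' @return Named numeric vector, percent of deposited dose.
#' @export
organ_burden <- function(traj, t, organs = traj$compartments) {
  a <- interp_amounts(traj, t)
  vapply(organs, function(o) {
    amt <- if (o == "lung") a[["lung_deposition"]] + a[["lung_tissue"]]
           else if (o %in% names(a)) a[[o]]
           else stop("unknown compartment: ", o)
    100 * amt / traj$dose
  }, numeric(1))
}

#' @export
print.pbpk_trajectory <- function(x, ...) {
  cat(sprintf("<pbpk_trajectory> %d time points over [%g, %g] h, dose %g (%s)\n",
              length(x$times), min(x$times), max(x$times), x$dose,
              x$exposure$route))
  invisible(x)
}

#' Tidy data frame representation of a trajectory
#'
#' @param x A `pbpk_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `time_h`, `compartment`,
#'   `amount_pct_dose`.
#' @export
as.data.frame.pbpk_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    time_h = rep(x$times, times = length(x$compartments)),
    compartment = rep(x$compartments, each = length(x$times)),
    amount_pct_dose = 100 * as.vector(x$amounts) / x$dose
  )
}

#' Write a trajectory to tidy CSV
#'
#' @param traj A `pbpk_trajectory`.
#' @param file Output path (`time_h,compartment,amount_pct_dose`).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  write.csv(as.data.frame(traj), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
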