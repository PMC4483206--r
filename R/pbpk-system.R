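# Compartmental system construction. The model is a linear, column-conservative
# generator matrix over 13 compartments; urine and feces are absorbing.

COMPARTMENTS <- c("lung_deposition", "blood", "lung_tissue", "liver", "spleen",
                  "kidneys", "heart", "brain", "GIT_tissue", "remainder",
                  "GIT_lumen", "urine", "feces")

# physiology organ name -> compartment name
organ_compartment <- function(organ) {
  ifelse(organ == "lung", "lung_tissue", organ)
}

#' Build the linear compartmental ODE system
#'
#' Assembles the first-order transfer-rate matrix from physiology and kinetic
#' rates. Organ uptake from blood is grouped by capillary wall type: the
#' blood-to-organ coefficient is `x_type(i) * Q_i / V_blood`, so organs that
#' share a capillary wall type share a permeability multiplier and the
#' transcapillary distribution is size-independent. Organ release back to
#' blood uses `k_release` (one global rate, or a named per-organ vector).
#' Deposited material leaves the lung-deposition pool to blood (`k_ab`,
#' epithelial translocation) or to the GIT lumen (`k_mc`, mucociliary
#' clearance); the liver additionally excretes to the GIT lumen via bile,
#' the kidneys to urine, and the GIT lumen empties into feces.
#'
#' @param phys A [load_physiology()] result.
#' @param rates A [kinetic_rates()] object, normally already passed through
#'   [apply_size_rules()].
#' @param particle Optional [particle_spec()] recorded for provenance.
#' @return An object of class `compartment_system` with elements
#'   `compartments`, `M` (rate matrix, 1/h, columns sum to zero),
#'   `phys`, `rates`, `particle`.
#' @export
#' @examples
#' sys <- build_system(load_physiology("rat"), load_kinetic_rates())
#' max(abs(colSums(sys$M)))  # conservative by construction
build_system <- function(phys, rates, particle = NULL) {
  stopifnot(inherits(phys, "physiology"), inherits(rates, "kinetic_rates"))
  if (!identical(phys$organs$organ, ORGANS)) {
    stop("physiology organ list does not match the model's compartments")
  }
  n <- length(COMPARTMENTS)
  M <- matrix(0, n, n, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  x <- c(continuous = rates$x_continuous, fenestrated = rates$x_fenestrated,
         sinusoidal = rates$x_sinusoidal)

  k_rel <- rates$k_release
  if (length(k_rel) == 1L && is.null(names(k_rel))) {
    k_rel <- setNames(rep(k_rel, nrow(phys$organs)), phys$organs$organ)
  } else if (!all(phys$organs$organ %in% names(k_rel))) {
    stop("per-organ k_release must name every organ")
  }

  for (i in seq_len(nrow(phys$organs))) {
    org <- phys$organs$organ[i]
    comp <- organ_compartment(org)
    M[comp, "blood"] <- x[[phys$organs$capillary_type[i]]] *
      phys$organs$blood_flow[i] / phys$blood_volume
    M["blood", comp] <- k_rel[[org]]
  }
  M["blood", "lung_deposition"] <- rates$k_ab
  M["GIT_lumen", "lung_deposition"] <- rates$k_mc
  M["GIT_lumen", "liver"] <- M["GIT_lumen", "liver"] + rates$k_bile
  M["urine", "kidneys"] <- M["urine", "kidneys"] + rates$k_urine
  M["urine", "blood"] <- M["urine", "blood"] + rates$k_filt
  M["feces", "GIT_lumen"] <- rates$k_git
  M["blood", "GIT_lumen"] <- rates$k_abs_git
  # absorbing sinks
  M[, "urine"] <- 0
  M[, "feces"] <- 0
  diag(M) <- 0
  diag(M) <- -colSums(M)

  structure(list(compartments = COMPARTMENTS, M = M, phys = phys,
                 rates = rates, particle = particle),
            class = "compartment_system")
}

#' Replace the lung-to-blood translocation rate of a built system
#'
#' Returns a copy of the system with `k_ab` (and the affected diagonal
#' entry) updated; used by the fitting routines and handy for rate sweeps.
#'
#' @param system A `compartment_system`.
#' @param k_ab New translocation rate, 1/h, `>= 0`.
#' @return The modified `compartment_system`.
#' @export
set_translocation_rate <- function(system, k_ab) {
  stopifnot(inherits(system, "compartment_system"), k_ab >= 0)
  set_kab(system, k_ab)
}

# replace k_ab in an already-built system (used by the 1-D fit)
set_kab <- function(system, k_ab) {
  M <- system$M
  M["blood", "lung_deposition"] <- k_ab
  M["lung_deposition", "lung_deposition"] <- 0
  M["lung_deposition", "lung_deposition"] <-
    -sum(M[-match("lung_deposition", rownames(M)), "lung_deposition"])
  system$M <- M
  system$rates$k_ab <- k_ab
  system
}

#' @export
print.compartment_system <- function(x, ...) {
  cat(sprintf("<compartment_system> %d compartments, k_ab = %g 1/h\n",
              length(x$compartments), x$M["blood", "lung_deposition"]))
  invisible(x)
}

#' Describe an exposure
#'
#' @param route `"instillation_bolus"` (all material in the lung deposition
#'   pool at t = 0) or `"inhalation_constant"` (constant deposition rate
#'   `deposited_dose / duration` for `t <= duration`).
#' @param deposited_dose Deposited dose; any mass unit (the trajectory carries
#'   the same unit). Use 100 to work directly in \% of dose.
#' @param duration Exposure duration in h; must be 0 for a bolus and > 0 for
#'   constant inhalation.
#' @return An object of class `exposure_event`.
#' @export
exposure_event <- function(route = c("instillation_bolus", "inhalation_constant"),
                           deposited_dose = 100, duration = 0) {
  route <- match.arg(route)
  stopifnot(is.numeric(deposited_dose), deposited_dose >= 0,
            is.numeric(duration), duration >= 0)
  if (route == "inhalation_constant" && duration <= 0) {
    stop("inhalation_constant requires duration > 0")
  }
  if (route == "instillation_bolus" && duration != 0) {
    stop("instillation_bolus requires duration == 0")
  }
  structure(list(route = route, deposited_dose = deposited_dose,
                 duration = duration),
            class = "exposure_event")
}

#' Export a compartment system as JSON
#'
#' Writes the rate matrix, compartment order and parameter provenance.
#'
#' @param system A `compartment_system`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_system <- function(system, file) {
  obj <- list(
    compartments = system$compartments,
    rate_matrix_per_h = unname(apply(system$M, 1, as.numeric, simplify = FALSE)),
    species = system$phys$species,
    rates = system$rates[RATE_NAMES],
    particle = if (!is.null(system$particle)) {
      list(core_diameter_nm = system$particle$core_diameter,
           charge_sign = system$particle$charge_sign,
           is_ionic = system$particle$is_ionic)
    }
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
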