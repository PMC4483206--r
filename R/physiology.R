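# Typed registries: particle properties, species physiology, kinetic rates.
# Default numeric tables ship as CSV under inst/extdata and are documented
# there as reconstructions; everything is user-replaceable.

ORGANS <- c("lung", "liver", "spleen", "kidneys", "heart", "brain",
            "GIT_tissue", "remainder")
CAPILLARY_TYPES <- c("continuous", "fenestrated", "sinusoidal")
RATE_NAMES <- c("x_continuous", "x_fenestrated", "x_sinusoidal", "k_release",
                "k_ab", "k_mc", "k_bile", "k_urine", "k_filt",
                "k_filt_enhanced", "k_git", "k_abs_git")

#' Describe a nanoparticle
#'
#' @param core_diameter Core diameter in nm. May be `NA` for an ionic control.
#' @param charge_sign One of `"negative"`, `"neutral"`, `"positive"`.
#' @param is_ionic Logical; `TRUE` for an ionic (dissolved metal) control,
#'   treated by the model as the limiting case of a vanishingly small particle.
#'
#' @return An object of class `particle_spec`.
#' @export
#' @examples
#' particle_spec(18)
#' particle_spec(NA, is_ionic = TRUE)
particle_spec <- function(core_diameter,
                          charge_sign = c("negative", "neutral", "positive"),
                          is_ionic = FALSE) {
  charge_sign <- match.arg(charge_sign)
  stopifnot(is.logical(is_ionic), length(is_ionic) == 1L)
  if (!is_ionic) {
    if (!is.numeric(core_diameter) || length(core_diameter) != 1L ||
        is.na(core_diameter) || core_diameter <= 0) {
      stop("'core_diameter' must be a single positive number unless is_ionic")
    }
  } else {
    core_diameter <- NA_real_
  }
  structure(list(core_diameter = as.numeric(core_diameter),
                 charge_sign = charge_sign,
                 is_ionic = is_ionic),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  if (x$is_ionic) {
    cat("<particle_spec> ionic control,", x$charge_sign, "charge\n")
  } else {
    cat(sprintf("<particle_spec> %g nm core, %s charge\n",
                x$core_diameter, x$charge_sign))
  }
  invisible(x)
}

read_param_csv <- function(path) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "value", "units", "gsd")
  if (!all(need %in% names(tab))) {
    stop("parameter table ", path, " must have columns ",
         paste(need, collapse = ","))
  }
  tab
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "translung")
  if (!nzchar(path)) stop("bundled table not found: ", file)
  path
}

#' Load species physiology
#'
#' Reads the per-species physiology table (body mass, blood volume, cardiac
#' output, organ blood flows) and the capillary wall type map, applies any
#' overrides, and validates the result. Overrides are applied before
#' validation, so an override that breaks an invariant is rejected with an
#' error naming the offending field.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param overrides Named list of replacement values. Scalar fields are named
#'   directly (`cardiac_output`); organ flows as `"<organ>.blood_flow"`;
#'   capillary types as `"<organ>.capillary_type"`.
#' @param path Optional path to a custom physiology CSV with header
#'   `name,value,units,gsd` (replaces the bundled table).
#' @param capillary_path Optional path to a custom `organ,capillary_type` CSV.
#'
#' @return An object of class `physiology`: species, `body_mass` (g),
#'   `blood_volume` (mL), `cardiac_output` (mL/h), an `organs` data frame
#'   (`organ`, `blood_flow` in mL/h, `capillary_type`), and per-parameter
#'   geometric standard deviations (`gsd`) for the uncertainty module.
#' @export
#' @examples
#' phys <- load_physiology("rat")
#' sum(phys$organs$blood_flow) <= phys$cardiac_output
load_physiology <- function(species = c("rat", "mouse"), overrides = list(),
                            path = NULL, capillary_path = NULL) {
  species <- match.arg(species)
  if (is.null(path)) path <- extdata(paste0("physiology_", species, ".csv"))
  if (is.null(capillary_path)) capillary_path <- extdata("capillary_types.csv")
  tab <- read_param_csv(path)
  vals <- setNames(as.numeric(tab$value), tab$name)
  gsd <- setNames(as.numeric(tab$gsd), tab$name)
  cap <- read.csv(capillary_path, comment.char = "#",
                  stringsAsFactors = FALSE)
  ctypes <- setNames(cap$capillary_type, cap$organ)

  known <- c("body_mass", "blood_volume", "cardiac_output",
             paste0(ORGANS, ".blood_flow"), paste0(ORGANS, ".capillary_type"))
  for (nm in names(overrides)) {
    if (!nm %in% known) stop("unknown physiology field in overrides: ", nm)
    if (endsWith(nm, ".capillary_type")) {
      ctypes[[sub("\\.capillary_type$", "", nm)]] <- overrides[[nm]]
    } else {
      vals[[nm]] <- as.numeric(overrides[[nm]])
    }
  }

  organs <- data.frame(
    organ = ORGANS,
    blood_flow = as.numeric(vals[paste0(ORGANS, ".blood_flow")]),
    capillary_type = as.character(ctypes[ORGANS]),
    stringsAsFactors = FALSE
  )
  phys <- structure(list(species = species,
                         body_mass = vals[["body_mass"]],
                         blood_volume = vals[["blood_volume"]],
                         cardiac_output = vals[["cardiac_output"]],
                         organs = organs,
                         gsd = gsd),
                    class = "physiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  for (fld in c("body_mass", "blood_volume", "cardiac_output")) {
    v <- phys[[fld]]
    if (!is.finite(v) || v <= 0) stop("physiology field must be > 0: ", fld)
  }
  bad <- !is.finite(phys$organs$blood_flow) | phys$organs$blood_flow <= 0
  if (any(bad)) {
    stop("physiology field must be > 0: ",
         paste0(phys$organs$organ[bad], ".blood_flow", collapse = ", "))
  }
  if (sum(phys$organs$blood_flow) > phys$cardiac_output) {
    stop("sum of organ blood flows exceeds cardiac_output")
  }
  bad <- !phys$organs$capillary_type %in% CAPILLARY_TYPES
  if (any(bad)) {
    stop("invalid capillary_type for: ",
         paste(phys$organs$organ[bad], collapse = ", "))
  }
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %g g; blood %g mL; cardiac output %g mL/h\n",
              x$species, x$body_mass, x$blood_volume, x$cardiac_output))
  print(x$organs, row.names = FALSE)
  invisible(x)
}

#' Write a physiology object back to its CSV representation
#'
#' Serializes in the same `name,value,units,gsd` format used by
#' [load_physiology()], so load -> write -> load round-trips.
#'
#' @param phys A `physiology` object.
#' @param file Output CSV path for the numeric table.
#' @param capillary_file Optional output path for the capillary type map.
#' @return `file`, invisibly.
#' @export
write_physiology <- function(phys, file, capillary_file = NULL) {
  nm <- c("body_mass", "blood_volume", "cardiac_output",
          paste0(phys$organs$organ, ".blood_flow"))
  units <- c("g", "mL", "mL/h", rep("mL/h", nrow(phys$organs)))
  val <- c(phys$body_mass, phys$blood_volume, phys$cardiac_output,
           phys$organs$blood_flow)
  gsd <- as.numeric(phys$gsd[nm])
  write.csv(data.frame(name = nm, value = val, units = units, gsd = gsd),
            file, row.names = FALSE, quote = FALSE)
  if (!is.null(capillary_file)) {
    write.csv(data.frame(organ = phys$organs$organ,
                         capillary_type = phys$organs$capillary_type),
              capillary_file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' Load kinetic rate constants
#'
#' Reads the first-order rate constant table (capillary permeability
#' multipliers, organ release, mucociliary/biliary/urinary clearance, GI
#' transit, lung-to-blood translocation) with overrides and validation.
#'
#' @param overrides Named list of replacement values for any rate.
#' @param path Optional path to a custom rate CSV (`name,value,units,gsd`).
#' @return An object of class `kinetic_rates`.
#' @export
load_kinetic_rates <- function(overrides = list(), path = NULL) {
  if (is.null(path)) path <- extdata("kinetic_rates.csv")
  tab <- read_param_csv(path)
  vals <- setNames(as.numeric(tab$value), tab$name)
  gsd <- setNames(as.numeric(tab$gsd), tab$name)
  for (nm in names(overrides)) {
    if (!nm %in% RATE_NAMES) stop("unknown kinetic rate in overrides: ", nm)
    vals[[nm]] <- as.numeric(overrides[[nm]])
  }
  do.call(kinetic_rates, c(as.list(vals[RATE_NAMES]), list(gsd = gsd)))
}

#' Construct a validated set of kinetic rates
#'
#' All rates are in 1/h except the dimensionless `x_*` capillary permeability
#' multipliers. Validation enforces non-negativity and the permeability
#' ordering sinusoidal >= fenestrated >= continuous.
#'
#' @param x_continuous,x_fenestrated,x_sinusoidal Capillary permeability
#'   multipliers (dimensionless) for the three capillary wall types.
#' @param k_release Organ-to-blood release rate (one global rate by default;
#'   the engine accepts a per-organ named vector too).
#' @param k_ab Lung-deposition-to-blood translocation rate (the fitted rate).
#' @param k_mc Mucociliary clearance rate, lung deposition -> GIT lumen.
#' @param k_bile Biliary excretion rate, liver -> GIT lumen.
#' @param k_urine Kidney -> urine rate.
#' @param k_filt Direct blood -> urine filtration rate (enhanced-renal mode;
#'   default 0, switched to `k_filt_enhanced` by [apply_size_rules()]).
#' @param k_filt_enhanced Value `k_filt` takes for particles below the renal
#'   threshold or ionic controls.
#' @param k_git GIT lumen -> feces transit rate.
#' @param k_abs_git GIT lumen -> blood absorption rate (default 0).
#' @param gsd Optional named numeric vector of geometric SDs per rate.
#' @return An object of class `kinetic_rates`.
#' @export
kinetic_rates <- function(x_continuous = 0.001, x_fenestrated = 0.01,
                          x_sinusoidal = 0.1, k_release = 0.01, k_ab = 0,
                          k_mc = 0.02, k_bile = 0.05, k_urine = 0.02,
                          k_filt = 0, k_filt_enhanced = 0.1, k_git = 0.05,
                          k_abs_git = 0, gsd = NULL) {
  r <- list(x_continuous = x_continuous, x_fenestrated = x_fenestrated,
            x_sinusoidal = x_sinusoidal, k_release = k_release, k_ab = k_ab,
            k_mc = k_mc, k_bile = k_bile, k_urine = k_urine, k_filt = k_filt,
            k_filt_enhanced = k_filt_enhanced, k_git = k_git,
            k_abs_git = k_abs_git)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("kinetic rate must be finite and >= 0: ", nm)
    }
  }
  if (!(r$x_sinusoidal >= r$x_fenestrated && r$x_fenestrated >= r$x_continuous)) {
    stop("capillary permeability must satisfy ",
         "x_sinusoidal >= x_fenestrated >= x_continuous")
  }
  r$gsd <- gsd
  r$warnings <- character(0)
  structure(r, class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("<kinetic_rates> (1/h unless dimensionless x_*)\n")
  flat <- unlist(x[RATE_NAMES])
  print(flat)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Apply particle-size applicability rules to a rate set
#'
#' Encodes the size limits of the capillary-pore transport picture:
#' particles larger than 150 nm cannot pass the liver capillary pores and are
#' hardly excreted in bile (`k_bile` is zeroed); particles below the renal
#' filtration threshold (default 5 nm, the reported critical diameter for
#' enhanced urinary excretion) and ionic controls get the enhanced direct
#' blood-to-urine rate. Outside the `[renal_threshold, 150]` nm window an
#' applicability warning is attached to the returned rates (the model then
#' under- or over-states renal/biliary handling).
#'
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param particle A [particle_spec()].
#' @param rates A [kinetic_rates()] object.
#' @param renal_threshold Renal filtration cut in nm (default 5).
#' @return A modified copy of `rates`; any applicability notes are in
#'   `$warnings`.
#' @export
apply_size_rules <- function(particle, rates, renal_threshold = 5) {
  stopifnot(inherits(particle, "particle_spec"),
            inherits(rates, "kinetic_rates"))
  out <- rates
  out$warnings <- character(0)
  d <- particle$core_diameter
  small <- particle$is_ionic || (!is.na(d) && d < renal_threshold)
  if (!particle$is_ionic && d > 150) {
    out$k_bile <- 0
    out$warnings <- c(out$warnings, sprintf(
      "diameter %g nm exceeds the 150 nm model limit (liver capillary pores); biliary excretion disabled", d))
  }
  if (small) {
    out$k_filt <- out$k_filt_enhanced
    out$warnings <- c(out$warnings, sprintf(
      "particle below the %g nm renal threshold (or ionic): enhanced renal filtration enabled; kidney and urine levels are uncertain", renal_threshold))
  }
  out
}
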