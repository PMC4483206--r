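# Shared fixtures, all built in code.

rat_phys <- function(overrides = list()) load_physiology("rat", overrides)

RATE_NAMES_vec <- function() {
  c("x_continuous", "x_fenestrated", "x_sinusoidal", "k_release", "k_ab",
    "k_mc", "k_bile", "k_urine", "k_filt", "k_filt_enhanced", "k_git",
    "k_abs_git")
}

default_system <- function(rate_overrides = list(), particle = particle_spec(18),
                           phys_overrides = list()) {
  rates <- apply_size_rules(particle, load_kinetic_rates(rate_overrides))
  build_system(rat_phys(phys_overrides), rates, particle)
}

bolus100 <- function() exposure_event("instillation_bolus", 100)

# randomized but valid rate set for property tests
random_rates <- function() {
  x <- sort(runif(3, 0.001, 0.2))
  kinetic_rates(x_continuous = x[1], x_fenestrated = x[2], x_sinusoidal = x[3],
                k_release = runif(1, 0, 0.2), k_ab = runif(1, 0, 0.5),
                k_mc = runif(1, 0, 0.5), k_bile = runif(1, 0, 0.3),
                k_urine = runif(1, 0, 0.3), k_filt = runif(1, 0, 0.1),
                k_git = runif(1, 0, 0.3), k_abs_git = runif(1, 0, 0.1))
}

# physiology tweak that removes uptake into the compartments excluded from
# the secondary-organ basis (lung tissue, GIT tissue), making
# measured_fraction == total_fraction exact when excretion is off
no_excluded_uptake <- function() {
  list("lung.blood_flow" = 1e-9, "GIT_tissue.blood_flow" = 1e-9)
}
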