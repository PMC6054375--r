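#' Multi-prey modified Holling type II intake rates
#'
#' Shared-saturation disc equation: the intake of prey j per unit predator
#' biomass is `C * a_j * rho_j / (1 + (C/g) * sum_k a_k * rho_k)` per day,
#' where `C` is the clearance rate, `g` the maximum intake rate and `rho`
#' the effective prey density. Total intake saturates at `g` as prey grow
#' dense and reduces to linear clearance `C * a * rho` when prey are scarce.
#'
#' @param clearance volume (or area) searched per unit predator biomass per
#'   day, in the same spatial units as `rho`.
#' @param max_intake g, day-1 maximum specific intake.
#' @param a availability vector in `[0, 1]`, one entry per prey.
#' @param rho effective prey density vector (biomass per m3 or per m2).
#' @return Per-prey specific intake rates (day-1), same length as `rho`.
#' @export
holling_intake <- function(clearance, max_intake, a, rho) {
  bs_validate(all(rho >= 0), "negative prey biomass")
  enc <- clearance * a * rho
  enc / (1 + sum(enc) / max_intake)
}

#' Effective available prey biomass for one predator stage in one box
#'
#' `B_eff = a * overlap * gape_ok * (1 - refuge) * B_prey`, where `overlap`
#' is the spatial/vertical co-occurrence factor, `gape_ok` is 1 when the mean
#' prey individual weight falls within the predator's gape window (biomass
#' pools use a fixed nominal size), and the refuge term is the
#' habitat-cover-weighted refuge fraction of the prey. Always within
#' `[0, B_prey]`.
#'
#' @param a availability scalar in `[0, 1]`.
#' @param B_prey prey biomass in the box.
#' @param prey_weight mean prey individual weight (same units as gape window
#'   reference, i.e. predator weight units).
#' @param pred_weight mean predator individual weight.
#' @param gape length-2 (min, max) prey:predator weight-ratio window.
#' @param refuge_frac habitat-weighted refuge fraction in `[0, 1]`.
#' @param overlap co-occurrence factor in `[0, 1]`.
#' @return Effective prey biomass.
#' @export
available_prey <- function(a, B_prey, prey_weight = NA, pred_weight = NA,
                           gape = c(0, Inf), refuge_frac = 0, overlap = 1) {
  g_ok <- 1
  if (!is.na(prey_weight) && !is.na(pred_weight) && pred_weight > 0) {
    r <- prey_weight / pred_weight
    g_ok <- as.numeric(r >= gape[1] & r <= gape[2])
  }
  a * overlap * g_ok * (1 - refuge_frac) * B_prey
}

#' Consume prey over one step (single predator stage, single box)
#'
#' Applies the modified Holling II intake to a list of prey, caps total prey
#' debits at the available mass with proportional rescaling, and returns the
#' realized intake per prey. Mass is exactly conserved: prey debits equal the
#' summed intake.
#'
#' @param pred_biomass predator biomass in the box (mass units).
#' @param clearance,max_intake,a as in [holling_intake()].
#' @param B_eff effective available prey biomass per prey (mass units).
#' @param volume the search volume (or area) converting biomass to density.
#' @param dt days (<= 1).
#' @return list(intake = realized mass consumed per prey,
#'   specific_rate = per-unit-biomass daily rates).
#' @export
consume <- function(pred_biomass, clearance, max_intake, a, B_eff, volume,
                    dt = 1) {
  bs_validate(pred_biomass >= 0 && all(B_eff >= 0), "negative biomass input")
  rho <- B_eff / volume
  rate <- holling_intake(clearance, max_intake, a, rho)
  demand <- rate * pred_biomass * dt
  cap <- pmin(1, B_eff / pmax(demand, .Machine$double.eps))
  list(intake = demand * cap, specific_rate = rate)
}

#' Assimilate intake into growth and waste
#'
#' Growth is `e * intake`; the unassimilated remainder `(1 - e) * intake` is
#' split between egestion (labile detritus) and excretion (ammonium) by the
#' configured egestion fraction. `intake = growth + detritus + NH4` exactly.
#'
#' @param intake consumed mass.
#' @param assim assimilation efficiency `e` in (0, 1].
#' @param egestion_frac share of waste egested as detritus.
#' @return list(growth, detritus, nh4).
#' @export
grow <- function(intake, assim, egestion_frac = 0.5) {
  bs_validate(assim > 0 && assim <= 1, "assimilation efficiency outside (0,1]")
  bs_validate(all(intake >= 0), "negative intake")
  waste <- (1 - assim) * intake
  list(growth = assim * intake, detritus = egestion_frac * waste,
       nh4 = (1 - egestion_frac) * waste)
}

#' Beverton-Holt recruitment with environmental scaling
#'
#' `R = phi_T * phi_S * phi_O2 * alpha * S / (beta + S)` where `S` is the
#' spawning-stock biomass (ogive-weighted) and each `phi` is a piecewise
#' linear 0-1 ramp between its configured bounds, evaluated on spawning
#' habitat conditions. For mammal/seabird-type groups the temperature and
#' salinity responses are disabled (phi = 1).
#'
#' @param S spawning-stock biomass, tons.
#' @param alpha recruits per year at saturation.
#' @param beta tons, half-saturation stock size (> 0).
#' @param env list of observed conditions `list(T=, S=, O2=)` (any subset).
#' @param ramps list of length-2 ramp bounds per driver, same names as `env`;
#'   drivers missing from `ramps` contribute phi = 1.
#' @return list(recruits, phi) where `phi` is the product scalar.
#' @export
recruit <- function(S, alpha, beta, env = list(), ramps = list()) {
  if (beta <= 0) bs_stop("Beverton-Holt beta must be > 0",
                         "baltisim_validation_error")
  phi <- 1
  for (d in names(ramps)) {
    if (!is.null(env[[d]])) phi <- phi * env_ramp(env[[d]], ramps[[d]])
  }
  list(recruits = phi * alpha * S / (beta + S), phi = phi)
}

#' Survivorship decay of cohort numbers
#'
#' Continuous mortality at annual rate Z applied over `dt` days:
#' `N * exp(-Z * dt / 365)`.
#'
#' @param numbers cohort numbers.
#' @param Z_yr total instantaneous mortality, yr-1 (natural + fishing).
#' @param dt days.
#' @return Surviving numbers.
#' @export
survive <- function(numbers, Z_yr, dt) numbers * exp(-Z_yr * dt / 365)

#' Annual ageing with a terminal plus-group
#'
#' Shifts numbers (and per-individual weights) up one cohort; the terminal
#' cohort accumulates as a plus-group with biomass-weighted mean weight; the
#' first cohort is emptied and reset to recruit weight until the next
#' spawning event.
#'
#' @param v vertebrate state: list(numbers, weight_s, weight_r).
#' @param recruit_weight mg N per individual for the emptied first cohort.
#' @param reserve_frac reserve share of recruit weight.
#' @return Updated state.
#' @export
age_cohorts <- function(v, recruit_weight, reserve_frac = 0.4) {
  n <- length(v$numbers)
  new_n <- c(0, v$numbers[-n])
  new_ws <- c(recruit_weight * (1 - reserve_frac), v$weight_s[-n])
  new_wr <- c(recruit_weight * reserve_frac, v$weight_r[-n])
  # plus-group merge
  Np <- v$numbers[n] + v$numbers[n - 1]
  if (Np > 0) {
    new_n[n] <- Np
    new_ws[n] <- (v$numbers[n] * v$weight_s[n] +
                    v$numbers[n - 1] * v$weight_s[n - 1]) / Np
    new_wr[n] <- (v$numbers[n] * v$weight_r[n] +
                    v$numbers[n - 1] * v$weight_r[n - 1]) / Np
  }
  v$numbers <- new_n; v$weight_s <- new_ws; v$weight_r <- new_wr
  v
}

#' Redistribute a stage over boxes by its quarterly map
#'
#' Replaces spatial shares with the map of the requested quarter, restricted
#' to boxes whose bottom oxygen admits the group (hypoxia avoidance) and
#' renormalized, conserving totals exactly. If no admissible box remains the
#' share vector is all zero (the caller treats the group as lost from the
#' domain).
#'
#' @param map per-box share vector summing to 1.
#' @param admissible logical per box.
#' @return Renormalized share vector (sums to 1, or to 0 if nothing is
#'   admissible).
#' @export
redistribute <- function(map, admissible = rep(TRUE, length(map))) {
  m <- map * as.numeric(admissible)
  s <- sum(m)
  if (s <= 0) return(m * 0)
  m / s
}
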