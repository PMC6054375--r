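#' Biogeochemical parameters
#'
#' Defaults for the nitrogen-currency biogeochemistry. Limitation of primary
#' production is a Liebig minimum of Michaelis-Menten nutrient and light
#' terms; ammonium is taken up before nitrate by strict sequential drawdown.
#' Implicit decay of labile and refractory detritus, sediment burial and
#' oxygen-gated sediment denitrification are the nitrogen sinks; nitrification
#' recycles ammonium to nitrate at an oxygen cost.
#'
#' @param lambda_L,lambda_R day-1 water-column decay of labile/refractory
#'   detritus (`lambda_R < lambda_L` enforced).
#' @param lambda_DON day-1 DON remineralization.
#' @param lambda_sed_L,lambda_sed_R day-1 sediment detritus remineralization.
#' @param burial day-1 loss of sediment detritus to permanent burial.
#' @param denit_rate day-1 first-order loss of sediment nitrate.
#' @param denit_O2_threshold mg O2 m-3 bottom-water gate below which
#'   denitrification is active.
#' @param nitrif_rate day-1 ammonium to nitrate (water and sediment).
#' @param nitrif_O2_min mg O2 m-3 below which nitrification stops.
#' @param k_w m-1 background light attenuation; `k_bio` m2 (mg N)-1 biological
#'   attenuation.
#' @param I_max W m-2 peak summer surface irradiance; `I_winter_frac` winter
#'   floor as a fraction of `I_max`.
#' @param air_sea_rate day-1 linear surface O2 relaxation towards saturation.
#' @return A `bs_bgc_params` list.
#' @export
bgc_params <- function(lambda_L = 0.03, lambda_R = 0.003, lambda_DON = 0.01,
                       lambda_sed_L = 0.02, lambda_sed_R = 0.0008,
                       burial = 1.2e-3, denit_rate = 0.06,
                       denit_O2_threshold = 4000,
                       nitrif_rate = 0.05, nitrif_O2_min = 500,
                       k_w = 0.18, k_bio = 2e-4,
                       I_max = 250, I_winter_frac = 0.04,
                       air_sea_rate = 0.3) {
  bs_validate(lambda_R < lambda_L, "lambda_R must be smaller than lambda_L")
  vals <- c(lambda_L, lambda_R, lambda_DON, lambda_sed_L, lambda_sed_R,
            burial, denit_rate, nitrif_rate, air_sea_rate)
  bs_validate(all(vals >= 0), "biogeochemical rates must be >= 0")
  bs_validate(k_w > 0 && k_bio >= 0, "k_w must be > 0 and k_bio >= 0")
  structure(list(lambda_L = lambda_L, lambda_R = lambda_R,
                 lambda_DON = lambda_DON, lambda_sed_L = lambda_sed_L,
                 lambda_sed_R = lambda_sed_R, burial = burial,
                 denit_rate = denit_rate,
                 denit_O2_threshold = denit_O2_threshold,
                 nitrif_rate = nitrif_rate, nitrif_O2_min = nitrif_O2_min,
                 k_w = k_w, k_bio = k_bio, I_max = I_max,
                 I_winter_frac = I_winter_frac, air_sea_rate = air_sea_rate),
            class = "bs_bgc_params")
}

#' Seasonal surface irradiance
#'
#' Theoretical net shortwave forcing reduced to a clipped annual cosine: peak
#' at the summer solstice, a small winter floor. Latitude enters only through
#' the configured amplitude (single-basin scale).
#'
#' @param doy day of year (1-365).
#' @param params a `bs_bgc_params`.
#' @return W m-2.
#' @export
surface_irradiance <- function(doy, params = bgc_params()) {
  s <- 0.5 * (1 + cos(2 * pi * (doy - 172) / 365))
  params$I_max * pmax(params$I_winter_frac, s^1.3)
}

#' Irradiance profile down a water column
#'
#' `I(z) = I0 * exp(-integral(k_w + k_bio * B(z) dz))` evaluated at layer
#' mid-depth; strictly decreasing with depth for positive `k_w`.
#'
#' @param I0 surface irradiance, W m-2 (>= 0).
#' @param biomass numeric vector of per-layer biological attenuator
#'   concentration (mg N m-3), top to bottom.
#' @param thickness per-layer thickness (m), same length.
#' @param params a `bs_bgc_params`.
#' @return W m-2 at each layer mid-depth.
#' @export
light_profile <- function(I0, biomass, thickness, params = bgc_params()) {
  bs_validate(I0 >= 0, "surface irradiance must be >= 0")
  bs_validate(all(biomass >= 0), "negative biomass in light profile")
  katt <- (params$k_w + params$k_bio * biomass) * thickness
  above <- c(0, cumsum(katt)[-length(katt)])
  I0 * exp(-(above + katt / 2))
}

# Benson-Krause style oxygen saturation, simplified for brackish water
o2_saturation <- function(temp, sal) {
  1000 * pmax(4, 14.62 - 0.3671 * temp + 0.0044972 * temp^2 -
                sal * (0.0966 - 0.00205 * temp))
}

# piecewise-linear 0-1 ramp between lo and hi
env_ramp <- function(x, bounds) {
  pmin(1, pmax(0, (x - bounds[1]) / (bounds[2] - bounds[1])))
}

#' One primary-producer growth increment (single cell)
#'
#' Growth is `mu_max * min(N_lim, I_lim) * B * dt` with Michaelis-Menten
#' nutrient (`N = NH4 + NO3`, ammonium drawn down first) and light terms.
#' Uptake debits exactly the nitrogen fixed; oxygen is produced in fixed
#' stoichiometric ratio. Uptake is capped at the available nutrient mass,
#' never producing negative concentrations.
#'
#' @param B producer biomass concentration, mg N m-3.
#' @param nh4,no3 nutrient concentrations, mg N m-3.
#' @param light W m-2 at the cell.
#' @param p producer parameter list (`mu_max`, `K_N`, `K_I`).
#' @param dt days.
#' @return list(growth, nh4_uptake, no3_uptake, o2_production) in
#'   concentration units.
#' @export
producer_step <- function(B, nh4, no3, light, p, dt) {
  bs_validate(all(c(B, nh4, no3) >= 0), "negative state in producer_step")
  N <- nh4 + no3
  n_lim <- N / (p$K_N + N)
  i_lim <- light / (p$K_I + light)
  growth <- p$mu_max * pmin(n_lim, i_lim) * B * dt
  growth <- pmin(growth, N)                  # cap at available nutrient
  u_nh4 <- pmin(growth, nh4)
  u_no3 <- growth - u_nh4
  list(growth = growth, nh4_uptake = u_nh4, no3_uptake = u_no3,
       o2_production = growth * baltisim_constants$o2_per_n_photo)
}

#' Detritus and DON remineralization (single pool, explicit Euler step)
#'
#' @param pool concentration or mass of the decaying pool.
#' @param lambda day-1.
#' @param dt days.
#' @return list(loss, remaining); the loss becomes ammonium (and consumes
#'   oxygen stoichiometrically in the full model step).
#' @export
remineralize <- function(pool, lambda, dt) {
  loss <- pmin(lambda * dt, 1) * pool
  list(loss = loss, remaining = pool - loss)
}

#' Sediment denitrification increment
#'
#' First-order loss of sediment nitrate, active only where bottom-water oxygen
#' is below the configured threshold; removed nitrogen leaves the system (the
#' denitrification ledger records it).
#'
#' @param no3_sed sediment nitrate mass (mg) per box.
#' @param bottom_o2 bottom-layer O2 (mg O2 m-3) per box.
#' @param params a `bs_bgc_params`.
#' @param dt days.
#' @return Vector of removed mg N per box.
#' @export
denitrify <- function(no3_sed, bottom_o2, params, dt) {
  gate <- as.numeric(bottom_o2 < params$denit_O2_threshold)
  pmin(params$denit_rate * dt, 1) * no3_sed * gate
}
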