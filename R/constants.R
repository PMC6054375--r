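#' Physical and stoichiometric constants
#'
#' Unit conversions used throughout the model. Nitrogen tracers are carried in
#' mg N m-3, oxygen in mg O2 m-3, and biomass is reported in metric tons of wet
#' weight with a single declared nitrogen content.
#'
#' @format A named list:
#' \describe{
#'   \item{mg_n_per_mmol}{14, molar mass of nitrogen (mg N per mmol N).}
#'   \item{mg_o2_per_mmol}{32, molar mass of molecular oxygen.}
#'   \item{mg_n_per_ton}{2.5e7, mg N per metric ton wet weight (2.5\% N content),
#'     the single biomass conversion used for all biota.}
#'   \item{o2_per_n_photo}{15.14, mg O2 produced (consumed) per mg N fixed
#'     (remineralized), Redfieldian 106 O2 : 16 N by mass.}
#'   \item{o2_per_n_nitrif}{4.57, mg O2 consumed per mg N nitrified (2 mol O2
#'     per mol N).}
#'   \item{ml_o2_per_l_to_mg_m3}{1429, conversion from mL O2 L-1 to mg O2 m-3.}
#' }
#' @export
baltisim_constants <- list(
  mg_n_per_mmol      = 14,
  mg_o2_per_mmol     = 32,
  mg_n_per_ton       = 2.5e7,
  o2_per_n_photo     = 106 * 32 / (16 * 14),
  o2_per_n_nitrif    = 2 * 32 / 14,
  ml_o2_per_l_to_mg_m3 = 1429
)

# water-column tracer order used in every TracerState array
TRACERS <- c("NO3", "NH4", "SiO4", "O2", "DON", "DL", "DR", "PS", "PL", "ZM")
# sediment pool order (total mass per box, mg)
SED_TRACERS <- c("NO3s", "NH4s", "DLs", "DRs")
# tracers subject to gravitational settling
SETTLING_TRACERS <- c("DL", "DR", "PL")
# minimum tracer set a serialized field file must contain
REQUIRED_TRACERS <- c("NO3", "NH4", "O2", "DL", "DR")

HABITATS <- c("bedrock", "sand", "mud", "manmade")

#' Internal stop helper carrying a condition class
#' @noRd
bs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "baltisim_error")))
}

#' @noRd
bs_validate <- function(ok, msg) {
  if (!ok) bs_stop(msg, "baltisim_validation_error")
  invisible(TRUE)
}
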