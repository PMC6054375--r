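#' Default biological functional-group configuration
#'
#' The shipped exemplar food web is a reduced, whole-basin configuration of
#' the full 30-group system, keeping the trophic backbone that the scenario
#' experiments exercise: two pelagic primary producers (PS small
#' phytoplankton; PL large phytoplankton, settling), mesozooplankton (ZM,
#' transported as a tracer), two benthic biomass pools (BD deposit feeders,
#' NE a Nephrops-type detritivore), and two age-structured fish groups (FSR,
#' a sprat-like planktivore with 5 cohorts; FCD, a cod-like bentho-piscivore
#' with 10 cohorts). Labile/refractory detritus and the nutrient pools close
#' the nitrogen cycle.
#'
#' Units follow the configuration conventions: rates per day unless suffixed
#' `_yr`; clearance in m3 per ton predator per day (pelagic) or m2 per ton per
#' day (benthic, against areal prey density); weights in mg N per individual;
#' biomass targets in metric tons wet weight; oxygen thresholds in mg O2 m-3.
#'
#' @return A `bs_groups` list with elements `producers`, `pools`, `verts`,
#'   `availability` (predator-stage x prey matrix), `refuge`
#'   (prey x habitat matrix) and `stoich` constants.
#' @export
default_groups <- function() {
  cnst <- baltisim_constants
  producers <- list(
    PS = list(name = "small phytoplankton", mu_max = 1.1, K_N = 25, K_I = 20,
              mort_lin = 0.08, mort_quad = 0, target_biomass = 6.4e6),
    PL = list(name = "large phytoplankton", mu_max = 1.3, K_N = 45, K_I = 35,
              mort_lin = 0.03, mort_quad = 1e-3, target_biomass = 5e5))
  pools <- list(
    ZM = list(name = "mesozooplankton", habitat = "pelagic",
              clearance = 1.7e5, max_intake = 0.4, assim = 0.3,
              mort_lin = 0.01, mort_quad = 1e-3,
              O2_min = 1500, hypoxia_mort = 0.1, target_biomass = 2.5e6),
    BD = list(name = "benthic deposit feeders", habitat = "benthic",
              clearance = 1.2e3, max_intake = 0.08, assim = 0.2,
              mort_lin = 0.003, mort_quad = 1e-5,
              O2_min = 2000, hypoxia_mort = 0.05, target_biomass = 5.3e6,
              habitat_affinity = c(bedrock = 0.1, sand = 0.6, mud = 1, manmade = 0)),
    NE = list(name = "Nephrops-type detritivore", habitat = "benthic",
              clearance = 3e2, max_intake = 0.03, assim = 0.25,
              mort_lin = 0.002, mort_quad = 2e-4,
              O2_min = 1500, hypoxia_mort = 0.03, target_biomass = 5.6e4,
              habitat_affinity = c(bedrock = 0, sand = 0.3, mud = 1, manmade = 0)))
  verts <- list(
    FSR = list(
      name = "sprat-like planktivore", n_cohorts = 5L, maturation_cohort = 3L,
      spawn_ogive = c(0.15, 0.8, 1, 1, 1),
      weights = c(50, 125, 200, 275, 325),      # mg N per individual
      reserve_frac = 0.4,                       # reserve share of weight
      clearance = c(2.5e5, 2.5e5, 1.5e5, 1.5e5, 1.5e5),
      max_intake = c(0.05, 0.045, 0.035, 0.03, 0.03),
      assim = 0.3,
      M_yr = rep(0.5, 5), F_adult_yr = 0.07, F_juv_yr = 0.035,
      BH_alpha = 1.6e12, BH_beta = 3e4,           # recruits yr-1; tons
      recruit_weight = 10, spawn_day = 150L, spawn_cost_frac = 0.5,
      env = list(T = c(2, 5), S = c(4, 6), O2 = c(1500, 2500)),
      O2_refuge = 300, gape = c(1e-9, 0.05),
      prey_nominal_weight = list(ZM = 1e-3),
      vertical = "pelagic", target_biomass = 1.5e6,
      spawn_habitat = "pelagic"),
    FCD = list(
      name = "cod-like bentho-piscivore", n_cohorts = 10L, maturation_cohort = 4L,
      spawn_ogive = c(0, 0, 0.1, 0.4, 0.8, 1, 1, 1, 1, 1),
      weights = c(750, 3750, 10000, 20000, 32500, 47500, 65000, 85000,
                  107500, 130000),
      reserve_frac = 0.4,
      clearance = c(rep(2e5, 3), rep(1e6, 7)),
      max_intake = c(rep(0.02, 3), rep(0.025, 7)),
      assim = 0.35,
      M_yr = rep(0.2, 10), F_adult_yr = 0.32, F_juv_yr = 0.16,
      BH_alpha = 2.8e9, BH_beta = 5e3,
      recruit_weight = 150, spawn_day = 110L, spawn_cost_frac = 0.5,
      env = list(T = c(1, 3), S = c(10, 12),
                 O2 = c(2 * 1429, 3 * 1429)),   # reproductive-volume anchors
      O2_refuge = 500, gape = c(2e-3, 0.3),
      prey_nominal_weight = list(ZM = 1e-3, BD = 150, NE = 300),
      vertical = "demersal", target_biomass = 2e5,
      spawn_habitat = "deep"))

  prey_names <- c("PS", "PL", "ZM", "DL", "DR", "DLs", "DRs", "BD", "NE",
                  "FSR", "FCD")
  stages <- c("ZM", "BD", "NE", "FSR_juv", "FSR_adult", "FCD_juv", "FCD_adult")
  A <- matrix(0, length(stages), length(prey_names),
              dimnames = list(stages, prey_names))
  A["ZM", c("PS", "PL")] <- c(1, 0)
  A["BD", c("DLs", "DRs")] <- c(1, 0.4)
  A["NE", c("DLs", "BD")] <- c(1, 0.15)
  A["FSR_juv", "ZM"] <- 1
  A["FSR_adult", "ZM"] <- 1
  A["FCD_juv", c("BD", "NE", "ZM")] <- c(1, 0.3, 0.3)
  A["FCD_adult", c("FSR", "BD", "FCD")] <- c(1, 0.15, 0.15)
  refuge <- matrix(0, length(prey_names), length(HABITATS),
                   dimnames = list(prey_names, HABITATS))
  refuge["BD", "bedrock"] <- 0.5
  refuge["NE", "bedrock"] <- 0.8

  structure(list(
    producers = producers, pools = pools, verts = verts,
    availability = A, refuge = refuge,
    # daily fraction of each benthic pool redistributed along its habitat
    # affinity (larval dispersal; recolonizes boxes after hypoxia retreats)
    pool_dispersal = 1e-3,
    stoich = list(egestion_frac = 0.5,      # share of unassimilated intake
                  o2_per_n = cnst$o2_per_n_photo,
                  mg_n_per_ton = cnst$mg_n_per_ton)),
    class = "bs_groups")
}

#' Names of all biological groups in a configuration
#' @param groups a `bs_groups`.
#' @return Character vector of group codes.
#' @export
group_names <- function(groups) {
  c(names(groups$producers), names(groups$pools), names(groups$verts))
}

#' Default synthetic initial-condition parameters
#' @return Named list: winter tracer concentrations, detritus fraction rule,
#'   map concentration for the seeded spatial allocations.
#' @export
default_ic_params <- function() {
  list(
    NO3 = c(surface = 60, deep = 180),
    NH4 = c(surface = 10, deep = 80),
    SiO4 = 400, O2_surface = 9500, O2_deep = 5000,
    DON = 50, plankton_seed = c(PS = 15, PL = 15, ZM = 20),
    detritus_frac = 0.1,   # initial water detritus as share of plankton stock
    sediment_mg_m2 = c(DLs = 3000, DRs = 150, NO3s = 500, NH4s = 500),
    map_jitter = 0.3)      # lognormal sd of the seeded spatial allocation
}

#' Generate synthetic initial conditions
#'
#' Builds winter tracer fields, benthic pool allocations restricted to
#' admissible habitat, cohort numbers and weights for age-structured groups,
#' and quarterly distribution maps per stage. Deterministic for a fixed seed;
#' per-group totals match the configured targets exactly; detrital pools are
#' purposefully initialized very low (a configured fraction of the plankton
#' standing stock) to avoid spurious early grazing.
#'
#' @param geom a validated `bs_geometry`.
#' @param groups a `bs_groups` configuration.
#' @param params see [default_ic_params()].
#' @param seed integer seed.
#' @return A `bs_initial_conditions` list: `tracers` (a `bs_tracer_state`),
#'   `pools` (matrix group x box, mg N), `verts` (per group: `numbers`,
#'   `weight_s`, `weight_r`), `maps` (per group, stage, quarter: per-box
#'   shares summing to 1).
#' @export
generate_initial_conditions <- function(geom, groups = default_groups(),
                                        params = default_ic_params(), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 2L)
  cnst <- baltisim_constants
  nb <- nrow(geom$boxes); nl <- geom$n_layers
  realized <- geom$thickness > 0
  dyn <- geom$dynamic

  st <- new_tracer_state(geom)
  fill_layered <- function(tr, surface, deep = surface) {
    sl <- matrix(NA_real_, nb, nl)
    for (l in seq_len(nl)) sl[, l] <- if (l == 1) surface else deep
    sl[!realized] <- NA
    st$conc[, , tr] <<- sl
  }
  fill_layered("NO3", params$NO3[["surface"]], params$NO3[["deep"]])
  fill_layered("NH4", params$NH4[["surface"]], params$NH4[["deep"]])
  fill_layered("SiO4", params$SiO4)
  fill_layered("O2", params$O2_surface, params$O2_deep)
  fill_layered("DON", params$DON)
  for (tr in c("PS", "PL", "ZM"))
    fill_layered(tr, params$plankton_seed[[tr]], params$plankton_seed[[tr]] * 0.3)
  # plankton biomass normalization to group targets (surface-weighted)
  for (tr in c("PS", "PL", "ZM")) {
    tgt <- if (tr == "ZM") groups$pools$ZM$target_biomass else
      groups$producers[[tr]]$target_biomass
    cur <- sum(st$conc[dyn, , tr] * geom$volume[dyn, ], na.rm = TRUE)
    st$conc[, , tr] <- st$conc[, , tr] * (tgt * cnst$mg_n_per_ton / cur)
  }
  # detritus: very low relative to plankton standing stock
  plank <- st$conc[, , "PS"] + st$conc[, , "PL"]
  st$conc[, , "DL"] <- params$detritus_frac * 0.6 * plank
  st$conc[, , "DR"] <- params$detritus_frac * 0.4 * plank
  # sediment pools seeded at typical standing levels (areal densities)
  for (trs in SED_TRACERS)
    st$sed[dyn, trs] <- params$sediment_mg_m2[[trs]] * geom$boxes$area[dyn]
  st$sed[geom$boundary, ] <- 0

  # benthic pools by habitat affinity
  pool_names <- setdiff(names(groups$pools), "ZM")
  pools <- matrix(0, length(pool_names), nb,
                  dimnames = list(pool_names, NULL))
  for (g in pool_names) {
    p <- groups$pools[[g]]
    aff <- as.matrix(geom$boxes[, HABITATS]) %*% p$habitat_affinity[HABITATS]
    w <- numeric(nb)
    w[dyn] <- aff[dyn] * geom$boxes$area[dyn] *
      exp(stats::rnorm(length(dyn), 0, params$map_jitter))
    if (sum(w) <= 0) bs_stop(sprintf(
      "group %s has no admissible habitat anywhere", g),
      "baltisim_validation_error")
    pools[g, ] <- p$target_biomass * cnst$mg_n_per_ton * w / sum(w)
  }

  # vertebrates: numbers at age from survivorship, scaled to target biomass
  verts <- list(); maps <- list()
  for (g in names(groups$verts)) {
    v <- groups$verts[[g]]
    a <- seq_len(v$n_cohorts)
    Z <- v$M_yr + ifelse(a >= v$maturation_cohort, v$F_adult_yr, v$F_juv_yr)
    surv <- exp(-cumsum(c(0, Z[-v$n_cohorts])))
    bio_per_rec <- sum(surv * v$weights)
    R <- v$target_biomass * cnst$mg_n_per_ton / bio_per_rec
    verts[[g]] <- list(
      numbers = R * surv,
      weight_s = v$weights * (1 - v$reserve_frac),
      weight_r = v$weights * v$reserve_frac)
    m <- array(0, c(2, 4, nb), dimnames = list(c("juv", "adult"), NULL, NULL))
    for (stg in 1:2) for (q in 1:4) {
      w <- numeric(nb)
      adm <- dyn
      if (identical(v$vertical, "demersal"))
        adm <- dyn[geom$boxes$max_depth[dyn] >= 10]
      w[adm] <- geom$boxes$area[adm] *
        exp(stats::rnorm(length(adm), 0, params$map_jitter))
      m[stg, q, ] <- w / sum(w)
    }
    maps[[g]] <- m
  }

  structure(list(tracers = st, pools = pools, verts = verts, maps = maps,
                 seed = seed),
            class = "bs_initial_conditions")
}
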