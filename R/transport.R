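#' Transport parameters
#'
#' @param vertical_mixing_rate m2 day-1, single domain-wide default diffusive
#'   rate across layer interfaces (per-box overrides via the `overrides`
#'   vector, 0-based box ids as names).
#' @param settling_velocity named m day-1 per settling tracer (labile and
#'   refractory detritus and large phytoplankton).
#' @param bioturbation_exchange day-1 linear sediment-bottom water solute
#'   exchange coefficient (bioirrigation, resuspension and erosion folded in).
#' @param sediment_porosity unitless porewater fraction of the sediment layer.
#' @return A `bs_transport_params` list.
#' @export
transport_params <- function(vertical_mixing_rate = 2.5,
                             settling_velocity = c(DL = 3, DR = 1, PL = 0.3),
                             bioturbation_exchange = 0.05,
                             sediment_porosity = 0.5,
                             overrides = NULL) {
  bs_validate(vertical_mixing_rate >= 0, "vertical mixing rate must be >= 0")
  bs_validate(all(overrides >= 0), "mixing overrides must be >= 0")
  bs_validate(all(settling_velocity >= 0), "settling velocities must be >= 0")
  bs_validate(bioturbation_exchange >= 0, "bioturbation exchange must be >= 0")
  bad <- setdiff(names(settling_velocity), SETTLING_TRACERS)
  if (length(bad)) bs_stop(sprintf(
    "settling applied to non-particulate tracer: %s", paste(bad, collapse = ",")),
    "baltisim_validation_error")
  structure(list(vertical_mixing_rate = vertical_mixing_rate,
                 settling_velocity = settling_velocity,
                 bioturbation_exchange = bioturbation_exchange,
                 sediment_porosity = sediment_porosity,
                 overrides = overrides),
            class = "bs_transport_params")
}

# Precomputed index structures for the transport operators. Cells are numbered
# box + nb*(layer-1); only realized cells carry state.
make_transport_plan <- function(geom) {
  nb <- nrow(geom$boxes); nl <- geom$n_layers
  cell <- function(b, l) b + nb * (l - 1L)          # b 1-based
  vol <- as.vector(geom$volume)                     # [cell]
  realized <- vol > 0
  f <- geom$faces
  # active (face, layer) pairs
  af <- list(face = integer(), layer = integer(),
             lcell = integer(), rcell = integer())
  if (nrow(f) > 0) {
    for (l in seq_len(nl)) {
      li <- f$left_box + 1L; ri <- f$right_box + 1L
      ok <- geom$thickness[li, l] > 0 & geom$thickness[ri, l] > 0
      if (!any(ok)) next
      af$face <- c(af$face, which(ok))
      af$layer <- c(af$layer, rep(l, sum(ok)))
      af$lcell <- c(af$lcell, cell(li[ok], l))
      af$rcell <- c(af$rcell, cell(ri[ok], l))
    }
  }
  # vertical interface pairs (up, down) with area/dz coefficient
  z <- geom$layers$interface_depths
  mid <- (c(0, z[-nl]) + z) / 2
  mix <- list(up = integer(), dn = integer(), coef = numeric())
  for (b in seq_len(nb)) {
    for (l in seq_len(nl - 1)) {
      if (geom$thickness[b, l + 1] <= 0) break
      dz <- mid[l + 1] - mid[l]
      mix$up <- c(mix$up, cell(b, l))
      mix$dn <- c(mix$dn, cell(b, l + 1))
      mix$coef <- c(mix$coef, geom$boxes$area[b] / dz)
    }
  }
  bottom_cell <- cell(seq_len(nb), geom$nlay)
  list(nb = nb, nl = nl, vol = vol, realized = realized,
       af = af, mix = mix, bottom_cell = bottom_cell,
       area = geom$boxes$area, nlay = geom$nlay,
       thickness = geom$thickness)
}

# conc matrix [cell, tracer] <-> TracerState array
conc_to_matrix <- function(state) {
  d <- dim(state$conc)
  matrix(state$conc, d[1] * d[2], d[3], dimnames = list(NULL, TRACERS))
}
matrix_to_conc <- function(M, state) {
  state$conc <- array(M, dim = dim(state$conc),
                      dimnames = dimnames(state$conc))
  state
}

# ---- core operators on the [cell, tracer] matrix ----

advect_core <- function(M, plan, flux) {
  if (!length(plan$af$face)) return(M)
  if (anyNA(flux)) bs_stop("NaN in exchange forcing", "baltisim_validation_error")
  q <- flux
  donor <- ifelse(q >= 0, plan$af$lcell, plan$af$rcell)
  recip <- ifelse(q >= 0, plan$af$rcell, plan$af$lcell)
  if (any(abs(q) > plan$vol[donor])) bs_stop(
    "CFL violation: |Q| dt exceeds donor cell volume; sub-step the exchange",
    "baltisim_cfl_error")
  mass <- abs(q) * M[donor, , drop = FALSE]
  idx <- c(donor, recip)
  delta <- rowsum(rbind(-mass, mass), group = idx)
  cells <- as.integer(rownames(delta))
  M[cells, ] <- M[cells, ] + delta / plan$vol[cells]
  M
}

# rate: scalar, or per-box vector applied by the box of each interface
vertical_mix_core <- function(M, plan, rate, dt) {
  if (any(rate < 0)) bs_stop("negative mixing rate", "baltisim_validation_error")
  if (all(rate == 0) || !length(plan$mix$up)) return(M)
  up <- plan$mix$up; dn <- plan$mix$dn
  if (length(rate) > 1) rate <- rate[((up - 1L) %% plan$nb) + 1L]
  k <- rate * plan$mix$coef                  # m3 day-1 exchange coefficient
  # explicit sub-stepping to keep the diffusion update stable
  r <- max(k * dt / pmin(plan$vol[up], plan$vol[dn]))
  nsub <- max(1L, ceiling(r / 0.4))
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    transfer <- (k * h) * (M[up, , drop = FALSE] - M[dn, , drop = FALSE])
    idx <- c(up, dn)
    delta <- rowsum(rbind(-transfer, transfer), group = idx)
    cells <- as.integer(rownames(delta))
    M[cells, ] <- M[cells, ] + delta / plan$vol[cells]
  }
  M
}

# settling moves mass downward between adjacent realized layers and from the
# deepest water layer into the sediment pools (PL settles into labile sediment
# detritus). Returns list(M, sed).
settle_core <- function(M, sed, plan, velocity, dt) {
  bad <- setdiff(names(velocity), SETTLING_TRACERS)
  if (length(bad)) bs_stop(sprintf(
    "settling applied to non-particulate tracer: %s", paste(bad, collapse = ",")),
    "baltisim_validation_error")
  up <- plan$mix$up; dn <- plan$mix$dn
  nb <- plan$nb
  for (tr in names(velocity)) {
    w <- velocity[[tr]]
    if (w <= 0) next
    # fraction leaving a cell per step, capped below 1 by construction
    thick_up <- plan$vol[up] / plan$area[((up - 1L) %% nb) + 1L]
    frac <- pmin(w * dt / thick_up, 1)
    if (length(up)) {
      mass <- frac * M[up, tr] * plan$vol[up]
      M[up, tr] <- M[up, tr] - mass / plan$vol[up]
      M[dn, tr] <- M[dn, tr] + mass / plan$vol[dn]
    }
    # deepest water layer -> sediment
    bc <- plan$bottom_cell
    thick_b <- plan$vol[bc] / plan$area
    fb <- pmin(w * dt / thick_b, 1)
    bmass <- fb * M[bc, tr] * plan$vol[bc]
    bmass[is.na(bmass)] <- 0
    M[bc, tr] <- M[bc, tr] - bmass / plan$vol[bc]
    dest <- if (tr == "DR") "DRs" else "DLs"
    sed[, dest] <- sed[, dest] + bmass
  }
  list(M = M, sed = sed)
}

# linear sediment-bottom water exchange of dissolved tracers (NO3, NH4)
sediment_exchange_core <- function(M, sed, plan, k, dt, porosity, sed_thick) {
  if (k <= 0) return(list(M = M, sed = sed))
  bc <- plan$bottom_cell
  vsed <- plan$area * sed_thick * porosity
  for (tr in c("NO3", "NH4")) {
    trs <- paste0(tr, "s")
    target <- M[bc, tr] * vsed
    dS <- k * dt * (target - sed[, trs])
    dS[is.na(dS)] <- 0
    # do not draw more than available on either side
    dS <- pmax(pmin(dS, M[bc, tr] * plan$vol[bc]), -sed[, trs])
    sed[, trs] <- sed[, trs] + dS
    M[bc, tr] <- M[bc, tr] - dS / plan$vol[bc]
  }
  list(M = M, sed = sed)
}

# ---- public operation wrappers on TracerState ----

#' Advect tracers by prescribed face exchange volumes
#'
#' First-order upwind donor-cell update: each face moves `Q * C_donor` of every
#' tracer. Total tracer mass over dynamic boxes changes only through faces
#' touching boundary boxes; a spatially uniform field is left exactly
#' unchanged by any balanced exchange field. Errors if any `|Q|` exceeds the
#' donor cell volume (CFL) or the forcing contains NaN.
#'
#' @param state a `bs_tracer_state`.
#' @param geom geometry.
#' @param flux matrix \code{[face, layer]} of signed m3 moved during the step
#'   (left-to-right positive).
#' @param tracers tracers to advect (default: all water tracers).
#' @return Updated `bs_tracer_state`.
#' @export
advect <- function(state, geom, flux, tracers = TRACERS) {
  plan <- make_transport_plan(geom)
  M <- conc_to_matrix(state)
  q <- flux[cbind(plan$af$face, plan$af$layer)]
  M2 <- M
  M2[, tracers] <- advect_core(M[, tracers, drop = FALSE], plan, q)
  matrix_to_conc(M2, state)
}

#' Diffusive vertical mixing between adjacent layers
#'
#' Exchange proportional to `rate * interface_area / interface_distance`;
#' column mass is conserved exactly and the across-layer variance of each
#' column is non-increasing. Sub-steps internally for stability.
#'
#' @param state a `bs_tracer_state`.
#' @param geom geometry.
#' @param params a `bs_transport_params` (or rate via `params$vertical_mixing_rate`).
#' @param dt days.
#' @return Updated state.
#' @export
vertical_mix <- function(state, geom, params, dt) {
  plan <- make_transport_plan(geom)
  M <- conc_to_matrix(state)
  M <- vertical_mix_core(M, plan, params$vertical_mixing_rate, dt)
  matrix_to_conc(M, state)
}

#' Particle settling
#'
#' Downward-only flux `w_s * C * area` between adjacent layers; flux out of the
#' deepest water layer enters the sediment detritus pools. Water plus sediment
#' mass is conserved exactly. Applying a settling velocity to a non-particulate
#' tracer is a validation error.
#'
#' @inheritParams vertical_mix
#' @return Updated state.
#' @export
settle <- function(state, geom, params, dt) {
  plan <- make_transport_plan(geom)
  M <- conc_to_matrix(state)
  out <- settle_core(M, state$sed, plan, params$settling_velocity, dt)
  state$sed <- out$sed
  matrix_to_conc(out$M, state)
}
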