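#' Default synthetic physics parameters
#'
#' Controls the seasonal structure of the generated forcing year. Coastal boxes
#' (bottom depth at or above `coastal_depth`) get a larger temperature
#' amplitude than offshore boxes so that coastal winter minima reach the
#' configured minimum (0 degC by default). Salinity declines monotonically
#' along the box-id axis from the entrance value, with a positive gradient
#' towards depth. Exchange volumes are a per-face seasonal sinusoid plus seeded
#' noise, projected per box and layer to zero net divergence (rigid-lid box
#' volumes), with winter maxima so that deep layers are ventilated by seasonal
#' inflows.
#'
#' @return Named list of parameters with units in field names.
#' @export
default_physics_params <- function() {
  list(
    coastal_depth      = 40,    # m; boxes shallower than this are "coastal"
    t_mean_coastal     = 8.5,   # degC surface annual mean, coastal
    t_amp_coastal      = 9.0,   # degC amplitude; winter minimum clamps at 0
    t_mean_offshore    = 8.0,
    t_amp_offshore     = 6.0,
    t_deep_mean        = 5.0,   # degC below the surface layer
    t_deep_amp         = 1.0,
    t_min              = 0.0,   # degC lower clamp
    sal_entrance       = 20.0,  # psu at the start of the axis (entrance)
    sal_axis_drop      = 14.0,  # psu total decline along the axis
    sal_depth_gain     = 0.04,  # psu per m of layer mid-depth
    exch_frac          = 0.001, # base face flux as fraction of donor volume/12h
    exch_seasonal      = 0.8,   # relative winter amplification of exchange
    exch_noise         = 0.3,   # relative sd of seeded lognormal noise
    boundary_exch_scale = 1.5,    # amplification of faces touching boundary
                                # boxes (episodic saline inflow events)
    cfl_frac           = 0.45,  # max |Q| dt / donor volume after projection
    boundary = list(            # boundary-box tracer climatology (mean, amp)
      NO3 = c(45, 20), NH4 = c(6, 2), SiO4 = c(400, 100),
      O2 = c(9500, 1500), DON = c(25, 5), DL = c(10, 5), DR = c(12, 3),
      PS = c(20, 15), PL = c(25, 20), ZM = c(12, 8))
  )
}

# evaluate a (mean, amp) seasonal pair at day-of-year; winter peak for
# nutrients/O2 (phase day 30), summer peak for plankton (phase day 200)
seasonal_value <- function(mean_amp, doy, phase_day) {
  mean_amp[1] + mean_amp[2] * cos(2 * pi * (doy - phase_day) / 365)
}

#' Generate one year of synthetic physics forcing
#'
#' Produces a 12-hour resolution annual cycle of temperature, salinity, signed
#' face exchange volumes and boundary-box tracer climatology. The same year is
#' reused for every projection year, so forcing is exactly annually periodic.
#' Per dynamic box and layer, the signed exchanges sum to zero at every step
#' (enforced by a graph-Laplacian divergence projection), which makes tracer
#' conservation under advection exactly testable.
#'
#' @param geom a validated `bs_geometry`.
#' @param params see [default_physics_params()].
#' @param seed integer seed; the result is a pure function of
#'   (geometry, params, seed).
#' @return A `bs_forcing` list: `temperature`, `salinity` arrays
#'   \code{[step, box, layer]}; `exchange` \code{[step, face, layer]} in m3 per
#'   12 h, signed left-to-right positive; `boundary` \code{[step, layer,
#'   tracer]}; `n_steps`, `dt_hours`.
#' @export
generate_physics <- function(geom, params = default_physics_params(), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  nb <- nrow(geom$boxes); nl <- geom$n_layers; nf <- nrow(geom$faces)
  n_steps <- 730L
  doy <- rep(seq_len(365), each = 2)
  coastal <- geom$boxes$max_depth <= params$coastal_depth
  z <- geom$layers$interface_depths
  mid <- (c(0, z[-nl]) + z) / 2

  temperature <- array(NA_real_, c(n_steps, nb, nl))
  salinity <- array(NA_real_, c(n_steps, nb, nl))
  # annual cycle peaks in late summer (day 220)
  cyc <- cos(2 * pi * (doy - 220) / 365)
  axis_pos <- (geom$boxes$box_id) / max(1, nb - 1)
  for (b in seq_len(nb)) {
    for (l in seq_len(nl)) {
      if (geom$thickness[b, l] <= 0) next
      if (l == 1) {
        tm <- if (coastal[b]) params$t_mean_coastal else params$t_mean_offshore
        ta <- if (coastal[b]) params$t_amp_coastal else params$t_amp_offshore
      } else {
        tm <- params$t_deep_mean; ta <- params$t_deep_amp
      }
      temperature[, b, l] <- pmax(params$t_min, tm + ta * cyc)
      sal <- params$sal_entrance - params$sal_axis_drop * axis_pos[b] +
        params$sal_depth_gain * mid[l]
      if (sal < 0) bs_stop(sprintf(
        "salinity parameters produce negative salinity in box %d", b - 1),
        "baltisim_validation_error")
      salinity[, b, l] <- sal
    }
  }

  # --- exchange volumes: seasonal template + noise, then projection ---
  exchange <- array(0, c(n_steps, nf, nl))
  if (nf > 0) {
    li <- geom$faces$left_box + 1L; ri <- geom$faces$right_box + 1L
    dt_frac <- params$exch_frac
    winter <- 1 + params$exch_seasonal * cos(2 * pi * (doy - 30) / 365)
    face_noise <- matrix(exp(stats::rnorm(nf * nl, 0, params$exch_noise)), nf, nl)
    face_sign <- matrix(sign(stats::rnorm(nf * nl)), nf, nl)
    for (l in seq_len(nl)) {
      act <- which(geom$thickness[li, l] > 0 & geom$thickness[ri, l] > 0)
      if (!length(act)) next
      vmin <- pmin(geom$volume[li[act], l], geom$volume[ri[act], l])
      bscale <- ifelse(geom$boxes$kind[li[act]] == "boundary" |
                         geom$boxes$kind[ri[act]] == "boundary",
                       params$boundary_exch_scale, 1)
      base <- dt_frac * vmin * face_noise[act, l] * face_sign[act, l] * bscale
      for (s in seq_len(n_steps)) exchange[s, act, l] <- base * winter[s]
      exchange[, , l] <- project_divergence_free(
        exchange[, , l, drop = TRUE], geom, l, act)
      # uniform per-step rescale to respect the CFL fraction
      for (s in seq_len(n_steps)) {
        q <- exchange[s, act, l]
        don <- ifelse(q >= 0, geom$volume[li[act], l], geom$volume[ri[act], l])
        r <- max(abs(q) / (params$cfl_frac * don), 1)
        if (max(r) > 1) exchange[s, act, l] <- q / max(r)
      }
    }
  }

  # --- boundary climatology ---
  boundary <- array(NA_real_, c(n_steps, nl, length(TRACERS)),
                    dimnames = list(NULL, NULL, TRACERS))
  for (tr in TRACERS) {
    phase <- if (tr %in% c("PS", "PL", "ZM")) 150 else 30
    v <- seasonal_value(params$boundary[[tr]], doy, phase)
    for (l in seq_len(nl)) {
      scale <- if (tr == "O2" && l > 2) 0.6 else 1
      boundary[, l, tr] <- pmax(0, v * scale)
    }
  }

  structure(list(n_steps = n_steps, dt_hours = 12,
                 temperature = temperature, salinity = salinity,
                 exchange = exchange, boundary = boundary,
                 coastal = coastal, params = params, seed = seed),
            class = "bs_forcing")
}

# zero the net signed flux into every dynamic box for one layer, all steps.
# Boundary boxes act as Dirichlet ground and absorb the residual.
project_divergence_free <- function(ex_layer, geom, layer, act) {
  if (!length(act)) return(ex_layer)
  nb <- nrow(geom$boxes)
  li <- geom$faces$left_box[act] + 1L; ri <- geom$faces$right_box[act] + 1L
  # graph Laplacian over boxes active in this layer
  Lmat <- matrix(0, nb, nb)
  for (k in seq_along(act)) {
    Lmat[li[k], li[k]] <- Lmat[li[k], li[k]] + 1
    Lmat[ri[k], ri[k]] <- Lmat[ri[k], ri[k]] + 1
    Lmat[li[k], ri[k]] <- Lmat[li[k], ri[k]] - 1
    Lmat[ri[k], li[k]] <- Lmat[ri[k], li[k]] - 1
  }
  active_boxes <- sort(unique(c(li, ri)))
  dyn <- intersect(active_boxes, geom$dynamic)
  has_bnd <- length(intersect(active_boxes, geom$boundary)) > 0
  solve_nodes <- dyn
  if (!has_bnd && length(dyn) > 1) solve_nodes <- dyn[-1]  # pin one node
  if (!length(solve_nodes)) return(ex_layer)
  Ls <- Lmat[solve_nodes, solve_nodes, drop = FALSE]
  Li <- solve(Ls)
  for (s in seq_len(nrow(ex_layer))) {
    q <- ex_layer[s, act]
    div <- numeric(nb)
    for (k in seq_along(act)) {
      div[ri[k]] <- div[ri[k]] + q[k]
      div[li[k]] <- div[li[k]] - q[k]
    }
    psi <- numeric(nb)
    psi[solve_nodes] <- Li %*% div[solve_nodes]
    ex_layer[s, act] <- q + (psi[li] - psi[ri])
  }
  ex_layer
}

#' Default riverine load parameters
#' @return Named list; see [generate_loads()].
#' @export
default_load_params <- function() {
  list(
    total_annual_tN   = 6e5,   # tons N yr-1 over all loaded boxes
    din_fraction      = 0.7,   # DIN share of total N (stand-in fractionation)
    retention_coastal = 0.30,  # coastal retention rho
    bioavailable_don  = 0.5,   # phi_bio, labile share of DON
    offshore_spill    = 0.3    # share redirected to the paired offshore box
  )
}

#' Generate a synthetic riverine nitrogen load table
#'
#' Annual totals are distributed over coastal dynamic boxes proportionally to
#' area with seeded lognormal variation. Loads are annually averaged but
#' applied daily at even rates; the effective daily DIN load to box b is
#' `annual_b * (1 - rho_b) * din_fraction / 365`, DON analogously with the
#' bioavailable fraction. A configured share of each coastal load is
#' redirected to the paired (deepest adjacent) offshore box.
#'
#' @param geom a validated `bs_geometry`.
#' @param params see [default_load_params()].
#' @param seed integer seed.
#' @return A `bs_loads` data.frame: `box_id`, `annual_total_tN`,
#'   `din_fraction`, `retention`, `bioavailable_don_fraction`,
#'   `offshore_spill_fraction`, `spill_target`.
#' @export
generate_loads <- function(geom, params = default_load_params(), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 1L)
  b <- geom$boxes
  coastal <- which(b$kind == "dynamic" & b$max_depth <= 40)
  if (!length(coastal)) coastal <- geom$dynamic
  w <- b$area[coastal] * exp(stats::rnorm(length(coastal), 0, 0.3))
  annual <- params$total_annual_tN * w / sum(w)
  spill_target <- vapply(coastal, function(i) {
    f <- geom$faces
    nb <- c(f$right_box[f$left_box == b$box_id[i]],
            f$left_box[f$right_box == b$box_id[i]])
    nb <- nb[nb %in% (geom$dynamic - 1L)]
    nb <- setdiff(nb, b$box_id[coastal])
    if (!length(nb)) return(NA_integer_)
    as.integer(nb[which.max(b$max_depth[nb + 1L])])
  }, integer(1))
  out <- data.frame(
    box_id = b$box_id[coastal],
    annual_total_tN = annual,
    din_fraction = params$din_fraction,
    retention = params$retention_coastal,
    bioavailable_don_fraction = params$bioavailable_don,
    offshore_spill_fraction = ifelse(is.na(spill_target), 0, params$offshore_spill),
    spill_target = spill_target)
  validate_loads(out, geom)
  class(out) <- c("bs_loads", "data.frame")
  out
}

#' @noRd
validate_loads <- function(loads, geom) {
  fr <- c("din_fraction", "retention", "bioavailable_don_fraction",
          "offshore_spill_fraction")
  for (f in fr) bs_validate(all(loads[[f]] >= 0 & loads[[f]] <= 1),
                            sprintf("%s outside [0,1]", f))
  bnd <- geom$boxes$box_id[geom$boundary]
  bs_validate(!any(loads$box_id %in% bnd),
              "river load assigned to a boundary box")
  invisible(TRUE)
}

#' Effective daily nitrogen loads per box
#'
#' Resolves retention, DIN/DON fractionation, bioavailability and offshore
#' spill redirection into per-box daily source terms. Nitrogen is conserved:
#' summed over boxes and streams, the annual effective load equals the summed
#' configured totals times (1 - retention), regardless of redirection. The
#' non-bioavailable DON share enters the refractory detritus stream.
#'
#' @param loads a `bs_loads` table.
#' @param geom the geometry.
#' @return Matrix \code{[box, c("DIN","DON","DR")]} of mg N per day.
#' @export
effective_daily_loads <- function(loads, geom) {
  nb <- nrow(geom$boxes)
  out <- matrix(0, nb, 3, dimnames = list(NULL, c("DIN", "DON", "DR")))
  mg_per_ton <- 1e9  # tons N -> mg N
  for (i in seq_len(nrow(loads))) {
    r <- loads[i, ]
    daily <- r$annual_total_tN * (1 - r$retention) / 365 * mg_per_ton
    din <- daily * r$din_fraction
    don <- daily * (1 - r$din_fraction) * r$bioavailable_don_fraction
    dr  <- daily * (1 - r$din_fraction) * (1 - r$bioavailable_don_fraction)
    tgt <- r$box_id + 1L
    sp <- r$offshore_spill_fraction
    stay <- 1 - sp
    out[tgt, ] <- out[tgt, ] + stay * c(din, don, dr)
    if (sp > 0 && !is.na(r$spill_target)) {
      ot <- r$spill_target + 1L
      out[ot, ] <- out[ot, ] + sp * c(din, don, dr)
    }
  }
  out
}

#' Atmospheric ammonium deposition source per box
#'
#' A spatially uniform, time-invariant areal deposition rate applied to the
#' surface layer only.
#'
#' @param geom a validated `bs_geometry`.
#' @param rate_mmol_m2_day areal rate in mmol NH4 m-2 day-1 (default 0.15).
#' @return Numeric vector per box of mg N per day.
#' @export
deposition_flux <- function(geom, rate_mmol_m2_day = 0.15) {
  bs_validate(rate_mmol_m2_day >= 0, "deposition rate must be >= 0")
  rate_mmol_m2_day * geom$boxes$area * baltisim_constants$mg_n_per_mmol
}
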