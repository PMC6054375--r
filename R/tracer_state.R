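#' Tracer state container
#'
#' Holds per-box, per-layer water-column concentrations and per-box sediment
#' pools. Water tracers: NO3, NH4, SiO4, DON, DL (labile detritus), DR
#' (refractory detritus) in mg N m-3; O2 in mg O2 m-3; PS, PL (small/large
#' phytoplankton) and ZM (mesozooplankton) as nitrogen biomass concentrations
#' in mg N m-3. Sediment pools (NO3s, NH4s, DLs, DRs) are total mass per box
#' in mg. Non-realized layers hold NA.
#'
#' @param geom a validated `bs_geometry`.
#' @param fill scalar or named vector of initial concentrations per tracer.
#' @param time model time in days (metadata).
#' @return A `bs_tracer_state`: list with `conc` array
#'   \code{[box, layer, tracer]}, `sed` matrix \code{[box, sed_tracer]}, `time`.
#' @export
new_tracer_state <- function(geom, fill = 0, time = 0) {
  nb <- nrow(geom$boxes); nl <- geom$n_layers
  conc <- array(NA_real_, dim = c(nb, nl, length(TRACERS)),
                dimnames = list(NULL, NULL, TRACERS))
  realized <- geom$thickness > 0
  if (length(fill) == 1 && is.null(names(fill))) fill <- setNames(rep(fill, length(TRACERS)), TRACERS)
  for (tr in TRACERS) {
    v <- if (tr %in% names(fill)) fill[[tr]] else 0
    sl <- matrix(NA_real_, nb, nl); sl[realized] <- v
    conc[, , tr] <- sl
  }
  sed <- matrix(0, nb, length(SED_TRACERS), dimnames = list(NULL, SED_TRACERS))
  structure(list(conc = conc, sed = sed, time = time), class = "bs_tracer_state")
}

#' Total tracer mass over dynamic boxes (mg)
#' @param state a `bs_tracer_state`.
#' @param geom the geometry it lives on.
#' @param tracers subset of tracer names (default all water tracers).
#' @param sediment include sediment pools.
#' @export
tracer_mass <- function(state, geom, tracers = TRACERS, sediment = TRUE) {
  dyn <- geom$dynamic
  m <- 0
  for (tr in tracers) {
    sl <- state$conc[, , tr] * geom$volume
    m <- m + sum(sl[dyn, ], na.rm = TRUE)
  }
  if (sediment) {
    sed_tr <- intersect(paste0(tracers, "s"), SED_TRACERS)
    if (length(sed_tr)) m <- m + sum(state$sed[dyn, sed_tr])
  }
  m
}

#' Write tracer fields to a long-format CSV
#'
#' One row per (box, layer, tracer) cell plus sediment rows (layer = "sed").
#' Values are written with full double precision so that a write-read round
#' trip is bit-exact. A header comment records the units.
#'
#' @param state a `bs_tracer_state`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_tracer_fields <- function(state, path) {
  nb <- dim(state$conc)[1]; nl <- dim(state$conc)[2]
  rows <- expand.grid(box = seq_len(nb) - 1L, layer = seq_len(nl) - 1L,
                      tracer = TRACERS, stringsAsFactors = FALSE)
  rows$value <- as.vector(state$conc)
  rows <- rows[!is.na(rows$value), ]
  sed <- expand.grid(box = seq_len(nb) - 1L, layer = "sed",
                     tracer = SED_TRACERS, stringsAsFactors = FALSE)
  sed$value <- as.vector(state$sed)
  rows$layer <- as.character(rows$layer)
  all <- rbind(rows, sed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# baltisim tracer fields; N tracers mg N m-3, O2 mg O2 m-3, sediment mg per box",
               sprintf("# time_days=%s", format(state$time, digits = 17)),
               "box,layer,tracer,value"), con)
  writeLines(sprintf("%d,%s,%s,%s", all$box, all$layer, all$tracer,
                     formatC(all$value, format = "g", digits = 17)), con)
  invisible(path)
}

#' Read tracer fields written by [write_tracer_fields()]
#'
#' @param path CSV path.
#' @param geom geometry the fields must conform to; box count and realized
#'   layers are validated against it.
#' @return A `bs_tracer_state`.
#' @export
read_tracer_fields <- function(path, geom) {
  if (!file.exists(path)) bs_stop(sprintf("tracer file not found: %s", path),
                                  "baltisim_io_error")
  lines <- readLines(path)
  meta <- grep("^# time_days=", lines, value = TRUE)
  time <- if (length(meta)) as.numeric(sub("^# time_days=", "", meta[1])) else 0
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                       colClasses = c("integer", "character", "character", "numeric"))
  bs_validate(all(c("box", "layer", "tracer", "value") %in% names(d)),
              "tracer file missing required columns")
  water <- d[d$layer != "sed", ]
  present <- unique(water$tracer)
  miss <- setdiff(REQUIRED_TRACERS, present)
  bs_validate(length(miss) == 0,
              sprintf("tracer file lacks required tracers: %s", paste(miss, collapse = ",")))
  nb <- nrow(geom$boxes)
  bs_validate(max(d$box) + 1 <= nb && length(unique(water$box)) == nb,
              sprintf("tracer file box count does not match geometry (%d boxes)", nb))
  st <- new_tracer_state(geom, time = time)
  idx <- cbind(water$box + 1L, as.integer(water$layer) + 1L,
               match(water$tracer, TRACERS))
  bs_validate(!anyNA(idx[, 3]), "tracer file contains unknown tracer names")
  bs_validate(all(geom$thickness[idx[, 1:2, drop = FALSE]] > 0),
              "tracer file assigns values to non-realized layers")
  st$conc[idx] <- water$value
  sed <- d[d$layer == "sed", ]
  if (nrow(sed)) {
    sidx <- cbind(sed$box + 1L, match(sed$tracer, SED_TRACERS))
    bs_validate(!anyNA(sidx[, 2]), "unknown sediment tracer names")
    st$sed[sidx] <- sed$value
  }
  st
}
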