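#' Equilibrium detection on an annual biomass series
#'
#' Fits a linear trend to the annual means over the terminal window and
#' reports the absolute drift per decade relative to the window mean. A
#' series whose annual means are constant (including a pure within-year
#' seasonal cycle) has zero drift.
#'
#' @param series numeric vector of annual means.
#' @param window_years years at the end of the series to evaluate
#'   (default 20).
#' @param threshold relative drift per decade below which the series counts
#'   as equilibrated (default 0.02).
#' @return list(flag, drift) where drift is the fractional change per decade;
#'   `flag` is NA for a zero-mean series.
#' @export
detect_equilibrium <- function(series, window_years = 20, threshold = 0.02) {
  bs_validate(length(series) >= 2, "series too short")
  w <- min(window_years, length(series))
  s <- utils::tail(series, w)
  m <- mean(s)
  if (m == 0) return(list(flag = NA, drift = NA_real_))
  slope <- stats::coef(stats::lm(s ~ seq_along(s)))[2]
  drift <- abs(slope * 10) / abs(m)
  list(flag = unname(drift < threshold), drift = unname(drift))
}

#' Terminal-to-initial biomass factor per group
#'
#' @param result a `bs_run`.
#' @param window terminal window (default 5).
#' @param band acceptable factor band (default `c(0.5, 2)`, boundary
#'   inclusive).
#' @return data.frame(group, initial, terminal, factor, flagged).
#' @export
biomass_factor <- function(result, window = 5, band = c(0.5, 2)) {
  ta <- rowSums(terminal_average(result, window))
  init <- result$initial$biomass[result$group_names]
  bs_validate(all(init > 0), "initial biomass must be positive")
  f <- ta / init
  data.frame(group = result$group_names, initial = unname(init),
             terminal = unname(ta), factor = unname(f),
             flagged = unname(f < band[1] | f > band[2]))
}

#' Emergent diet composition from the feeding ledger
#'
#' Prey fractions of total consumed mass per predator stage over the last
#' `last_n_years` of a run. The diet is never read from configuration: it is
#' the realized ledger of feeding events.
#'
#' @param result a `bs_run`.
#' @param stage predator stage name (a row of the availability matrix, e.g.
#'   `"FCD_adult"`); NULL returns all stages.
#' @param last_n_years averaging window (default 5).
#' @return Named numeric vector of fractions summing to 1 over consumed prey,
#'   or NA-flagged if the stage consumed nothing; with `stage = NULL` a
#'   matrix of fractions per stage.
#' @export
diet_composition <- function(result, stage = NULL, last_n_years = 5) {
  yrs <- seq(result$years - last_n_years + 1, result$years)
  tot <- apply(result$diet[yrs, , , drop = FALSE], c(2, 3), sum)
  frac_of <- function(v) {
    s <- sum(v)
    if (s <= 0) return(setNames(rep(NA_real_, length(v)), names(v)))
    v / s
  }
  if (is.null(stage)) return(t(apply(tot, 1, frac_of)))
  bs_validate(stage %in% rownames(tot), sprintf("unknown stage %s", stage))
  frac_of(tot[stage, ])
}

#' Cohort demography report
#'
#' Terminal-average numbers per cohort for an age-structured group, with a
#' monotonicity flag: TRUE when numbers decrease strictly with age (the
#' terminal plus-group is exempt).
#'
#' @param result a `bs_run`.
#' @param group vertebrate group name.
#' @param window terminal years to average (default 5).
#' @return list(numbers, monotone).
#' @export
demography_report <- function(result, group, window = 5) {
  bs_validate(group %in% names(result$numbers),
              sprintf("%s is not an age-structured group", group))
  nm <- result$numbers[[group]]
  yrs <- seq(nrow(nm) - window + 1, nrow(nm))
  n <- colMeans(nm[yrs, , drop = FALSE])
  k <- length(n)
  mono <- if (k <= 2) TRUE else all(diff(n[seq_len(k - 1)]) < 0)
  list(numbers = n, monotone = mono)
}

#' Spatial persistence check
#'
#' Flags (group, box) pairs whose terminal-average biomass falls below the
#' persistence floor while the group's distribution maps assign that box a
#' nonzero share in at least one quarter and the group actually occupied the
#' box earlier in the run (extinction is disappearance, not never-presence:
#' boxes the group always avoided, e.g. hypoxic ones, are not flagged).
#' Seasonal zeros caused by migration (zero map share in the relevant
#' quarters) are not flagged either.
#'
#' @param result a `bs_run`.
#' @param floor_frac persistence floor as a fraction of initial group biomass
#'   (default 1e-6).
#' @param window terminal years (default 5).
#' @return data.frame of flagged (group, box) pairs (zero rows if none).
#' @export
persistence_check <- function(result, floor_frac = 1e-6, window = 5) {
  ta <- terminal_average(result, window)
  dynb <- result$geometry$dynamic
  flags <- list()
  for (g in result$group_names) {
    floor_val <- floor_frac * result$initial$biomass[[g]]
    if (g %in% names(result$maps)) {
      share <- apply(result$maps[[g]], 3, max)   # max over stages, quarters
      expected <- which(share > 0)
    } else {
      expected <- dynb
    }
    ever <- which(apply(result$annual_biomass[, g, , drop = FALSE], 3, max)
                  >= floor_val)
    low <- intersect(intersect(expected, ever),
                     which(ta[g, ] < floor_val))
    low <- intersect(low, dynb)
    if (length(low)) flags[[g]] <- data.frame(group = g, box = low - 1L,
                                              terminal = ta[g, low])
  }
  if (!length(flags)) return(data.frame(group = character(), box = integer(),
                                        terminal = numeric()))
  do.call(rbind, flags)
}

#' Full calibration report
#'
#' Bundles the calibration-quality criteria into one pure function of a run:
#' equilibrium flags and drifts per group, biomass factors against the band,
#' emergent diet fractions, demography monotonicity, persistence flags and a
#' bottom-oxygen summary per box.
#'
#' @param result a `bs_run`.
#' @param window terminal window (default 5).
#' @param band biomass factor band (default `c(0.5, 2)`).
#' @return A `bs_calibration_report` list.
#' @export
calibration_report <- function(result, window = 5, band = c(0.5, 2)) {
  eq <- lapply(result$group_names, function(g) {
    series <- rowSums(result$annual_biomass[, g, , drop = FALSE])
    detect_equilibrium(series)
  })
  names(eq) <- result$group_names
  demo <- lapply(names(result$numbers), function(g) demography_report(result, g))
  names(demo) <- names(result$numbers)
  yrs <- seq(result$years - window + 1, result$years)
  structure(list(
    equilibrium = data.frame(
      group = result$group_names,
      flag = vapply(eq, function(x) isTRUE(x$flag), TRUE),
      drift = vapply(eq, function(x) x$drift, 0)),
    biomass = biomass_factor(result, window, band),
    diet = diet_composition(result, NULL, window),
    demography = demo,
    persistence = persistence_check(result, window = window),
    bottom_o2 = data.frame(
      box = seq_len(ncol(result$bottom_o2)) - 1L,
      mean = colMeans(result$bottom_o2[yrs, , drop = FALSE]),
      min = apply(result$bottom_o2[yrs, , drop = FALSE], 2, min))),
    class = "bs_calibration_report")
}
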