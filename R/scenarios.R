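#' Define a scenario
#'
#' A scenario is a set of per-box river-load multipliers (1 minus the
#' percentage reduction) and/or fishing-mortality overrides per group, applied
#' instantaneously at the change year and held to the end of the horizon.
#' When a juvenile override is not given it defaults to half the adult
#' override.
#'
#' @param name scenario name.
#' @param load_multiplier named numeric vector, names are 0-based box ids,
#'   values in `[0, 1]`.
#' @param F_overrides list per group, each `list(adult =, juvenile =)` yr-1.
#' @param change_year year at which the intervention switches on (default 35).
#' @param horizon_years total run length (default 60).
#' @param terminal_window years averaged at the end of the run (default 5).
#' @return A `bs_scenario`.
#' @export
bs_scenario <- function(name, load_multiplier = numeric(0),
                        F_overrides = list(), change_year = 35,
                        horizon_years = 60, terminal_window = 5) {
  bs_validate(all(load_multiplier >= 0 & load_multiplier <= 1),
              "load multipliers must lie in [0, 1]")
  bs_validate(change_year < horizon_years,
              "change_year must precede the horizon")
  bs_validate(terminal_window >= 1 &&
                terminal_window <= horizon_years - change_year + terminal_window,
              "terminal window too long")
  for (g in names(F_overrides)) {
    ov <- F_overrides[[g]]
    bs_validate(!is.null(ov$adult) && ov$adult >= 0,
                sprintf("adult F override missing or negative for %s", g))
    if (is.null(ov$juvenile)) F_overrides[[g]]$juvenile <- ov$adult / 2
  }
  structure(list(name = name, load_multiplier = load_multiplier,
                 F_overrides = F_overrides, change_year = change_year,
                 horizon_years = horizon_years,
                 terminal_window = terminal_window),
            class = "bs_scenario")
}

#' The shipped ten-scenario catalog
#'
#' Scenario #1 is the status quo. #2-#5 are river nitrogen load reductions:
#' #2 reduces boxes 1, 2, 4 by 12/33/24 percent; #3 reduces boxes 1-4 by 33
#' percent; #4 is a regional action-plan-style set (9/20/15/32 percent on boxes
#' 1-4, 21.4/23 percent on boxes 5 and 9, 19 percent on boxes 12 and 13,
#' 35/33 percent on boxes 14 and 17); #5 is a pan-Baltic 33 percent cut on
#' every dynamic box. #6-#10 change fishing mortality: halved adult F for the
#' predator (0.16) and the prey fish (0.035), the doubled printed values
#' (0.64, 0.14), and the maximum observed pressure (1.2 predator, 0.6 prey
#' fish), juvenile F always half the new adult value. Halved values are
#' computed from the configured baselines (0.32, 0.07) by the 50 percent
#' rule. Boxes named in a catalog entry but absent from the geometry are
#' dropped (reduced geometries map the remaining coastal pattern).
#'
#' @param geom a validated `bs_geometry` (box existence check).
#' @param groups a `bs_groups`; baseline F values are read from the predator
#'   (`FCD`) and prey-fish (`FSR`) entries.
#' @return Named list of ten `bs_scenario` objects.
#' @export
build_scenarios <- function(geom = example_geometry("mini8"),
                            groups = default_groups()) {
  f_cod <- groups$verts$FCD$F_adult_yr
  f_spr <- groups$verts$FSR$F_adult_yr
  dynamic_ids <- geom$boxes$box_id[geom$dynamic]
  red <- function(ids, pct) {
    if (any(ids %in% geom$boxes$box_id[geom$boundary])) bs_stop(
      "load reduction assigned to a boundary box", "baltisim_validation_error")
    keep <- ids %in% dynamic_ids
    m <- 1 - pct[keep] / 100
    names(m) <- ids[keep]
    m
  }
  list(
    status_quo = bs_scenario("status_quo"),
    scenario2 = bs_scenario("scenario2",
                            red(c(1, 2, 4), c(12, 33, 24))),
    scenario3 = bs_scenario("scenario3", red(1:4, rep(33, 4))),
    scenario4 = bs_scenario("scenario4",
                            red(c(1, 2, 3, 4, 5, 9, 12, 13, 14, 17),
                                c(9, 20, 15, 32, 21.4, 23, 19, 19, 35, 33))),
    scenario5 = bs_scenario("scenario5",
                            stats::setNames(rep(1 - 0.33, length(dynamic_ids)),
                                            dynamic_ids)),
    scenario6 = bs_scenario("scenario6",
                            F_overrides = list(FCD = list(adult = f_cod / 2))),
    scenario7 = bs_scenario("scenario7",
                            F_overrides = list(FSR = list(adult = f_spr / 2))),
    scenario8 = bs_scenario("scenario8",
                            F_overrides = list(FCD = list(adult = 0.64))),
    scenario9 = bs_scenario("scenario9",
                            F_overrides = list(FSR = list(adult = 0.14))),
    scenario10 = bs_scenario("scenario10",
                             F_overrides = list(FCD = list(adult = 1.2),
                                                FSR = list(adult = 0.6))))
}

#' Terminal average of annual means
#'
#' Arithmetic mean over the last `window` years of the annual per-group,
#' per-box biomass of a run.
#'
#' @param result a `bs_run`.
#' @param window number of terminal years (default the scenario's window or 5).
#' @return Matrix \code{[group, box]} of tons.
#' @export
terminal_average <- function(result, window = NULL) {
  if (is.null(window))
    window <- if (!is.null(result$scenario)) result$scenario$terminal_window else 5
  bs_validate(window >= 1, "terminal window must be >= 1")
  bs_validate(window <= result$years, "window exceeds run length")
  yrs <- seq(result$years - window + 1, result$years)
  apply(result$annual_biomass[yrs, , , drop = FALSE], c(2, 3), mean)
}

#' Compare a scenario run against a baseline run
#'
#' Percent change of terminal-average domain biomass per group, per-box
#' bottom-oxygen change, and per-stock per-area biomass indices in two
#' averaging variants: (i) the plain sum of per-box terminal biomass over the
#' area's boxes, and (ii) a quarter-weighted variant respecting the seasonal
#' distribution maps of age-structured groups (identical to (i) when the maps
#' are quarter-invariant). A group with zero baseline terminal biomass is
#' flagged undefined rather than reported as an infinite change.
#'
#' @param result scenario `bs_run`.
#' @param baseline baseline `bs_run` (same geometry and groups).
#' @param window terminal window (default scenario's).
#' @param areas named list of 0-based box-id vectors defining assessment
#'   areas for the stock indices.
#' @return A `bs_comparison`: list(groups, bottom_o2, stock_indices).
#' @export
compare <- function(result, baseline, window = NULL,
                    areas = list(KA = 1, WB = c(2, 3), KAWB = 1:4)) {
  bs_validate(identical(result$group_names, baseline$group_names),
              "runs do not share a group list")
  bs_validate(nrow(result$geometry$boxes) == nrow(baseline$geometry$boxes),
              "runs do not share a geometry")
  ta_s <- terminal_average(result, window)
  ta_b <- terminal_average(baseline, window)
  tot_s <- rowSums(ta_s); tot_b <- rowSums(ta_b)
  undefined <- tot_b <= 0
  pct <- ifelse(undefined, NA_real_, 100 * (tot_s - tot_b) / tot_b)
  groups_df <- data.frame(group = result$group_names,
                          baseline = tot_b, scenario = tot_s,
                          pct_change = pct, undefined = undefined)
  w <- if (is.null(window)) {
    if (!is.null(result$scenario)) result$scenario$terminal_window else 5
  } else window
  yrs <- seq(result$years - w + 1, result$years)
  o2_s <- colMeans(result$bottom_o2[yrs, , drop = FALSE])
  o2_b <- colMeans(baseline$bottom_o2[yrs, , drop = FALSE])
  o2_df <- data.frame(box = seq_along(o2_s) - 1L, baseline = o2_b,
                      scenario = o2_s, delta = o2_s - o2_b)
  # stock-area indices, both averaging variants
  idx <- list()
  for (g in result$group_names) {
    for (an in names(areas)) {
      bx <- areas[[an]] + 1L
      plain_b <- sum(ta_b[g, bx]); plain_s <- sum(ta_s[g, bx])
      if (g %in% names(result$maps)) {
        shr_s <- mean(vapply(1:4, function(q)
          sum(result$maps[[g]]["adult", q, bx]), 0))
        shr_b <- mean(vapply(1:4, function(q)
          sum(baseline$maps[[g]]["adult", q, bx]), 0))
        mig_b <- tot_b[g] * shr_b; mig_s <- tot_s[g] * shr_s
      } else {
        mig_b <- plain_b; mig_s <- plain_s
      }
      idx[[length(idx) + 1]] <- data.frame(
        group = g, area = an,
        index_plain = if (plain_b > 0) 100 * (plain_s - plain_b) / plain_b else NA_real_,
        index_migration = if (mig_b > 0) 100 * (mig_s - mig_b) / mig_b else NA_real_)
    }
  }
  structure(list(groups = groups_df, bottom_o2 = o2_df,
                 stock_indices = do.call(rbind, idx)),
            class = "bs_comparison")
}
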