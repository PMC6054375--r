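#' Default stock input table for the bio-economic model
#'
#' Stocks are held at constant biomass over the economic projection; the
#' ecosystem model enters only through relative biomass scaling indices.
#' Shipped values are plausible 2012-style magnitudes for a Kattegat /
#' Western Baltic fishery on the groups the ecosystem model resolves
#' (predator fish split by area, prey fish and a Nephrops-type stock).
#'
#' @return data.frame with columns stock_id, group, area, TSB (tons),
#'   TSB_ref (base-year reference biomass for the catch production
#'   normalization; scaling indices change TSB, never TSB_ref), F, M (yr-1),
#'   TAC (tons), price (EUR per ton).
#' @export
default_stocks <- function() {
  data.frame(
    stock_id = c("COD_KA", "COD_WB", "SPR_KAWB", "NEP_KAWB"),
    group = c("FCD", "FCD", "FSR", "NE"),
    area = c("KA", "WB", "KAWB", "KAWB"),
    TSB = c(12000, 22000, 250000, 6000),
    TSB_ref = c(12000, 22000, 250000, 6000),
    F = c(0.4, 0.5, 0.3, 0.2),
    M = c(0.2, 0.2, 0.4, 0.3),
    TAC = c(2500, 6500, 45000, 900),
    price = c(1800, 1700, 250, 9000))
}

#' Default fleet segment table
#'
#' Four Danish-style segments (three trawler length classes and a
#' netter/liner class) with Cobb-Douglas intercepts in tons at reference
#' effort and stock size, cost structure per line item, quota shares per
#' stock and Kattegat / Western Baltic activity keys.
#'
#' @return A `bs_fleets` list of fleet definitions.
#' @export
default_fleets <- function() {
  fleet <- function(id, effort, max_effort, cd, costs, quota, keys) {
    list(fleet_id = id, effort = effort, max_effort = max_effort,
         effort_ref = effort, cobb_douglas = cd, costs = costs,
         quota_share = quota, area_keys = keys)
  }
  cd <- function(A, alpha = 1, beta = 1) list(A = A, alpha_E = alpha, beta_B = beta)
  structure(list(
    fleet("trawl12_15", 3200, 6000,
          list(COD_KA = cd(420), COD_WB = cd(700), SPR_KAWB = cd(3500),
               NEP_KAWB = cd(168)),
          list(fuel_per_day = 350, variable_per_day = 250, crew_share = 0.30,
               fixed_per_year = 4.0e5, capital_per_year = 2.5e5),
          c(COD_KA = 0.20, COD_WB = 0.15, SPR_KAWB = 0.05, NEP_KAWB = 0.25),
          c(KA = 0.55, WB = 0.45)),
    fleet("trawl15_18", 2800, 5500,
          list(COD_KA = cd(630), COD_WB = cd(980), SPR_KAWB = cd(8400),
               NEP_KAWB = cd(210)),
          list(fuel_per_day = 600, variable_per_day = 350, crew_share = 0.30,
               fixed_per_year = 5.5e5, capital_per_year = 3.5e5),
          c(COD_KA = 0.25, COD_WB = 0.20, SPR_KAWB = 0.15, NEP_KAWB = 0.35),
          c(KA = 0.50, WB = 0.50)),
    fleet("trawl18_24", 2600, 5000,
          list(COD_KA = cd(770), COD_WB = cd(1260), SPR_KAWB = cd(16800),
               NEP_KAWB = cd(252)),
          list(fuel_per_day = 1000, variable_per_day = 500, crew_share = 0.28,
               fixed_per_year = 7.5e5, capital_per_year = 5.0e5),
          c(COD_KA = 0.30, COD_WB = 0.30, SPR_KAWB = 0.55, NEP_KAWB = 0.30),
          c(KA = 0.45, WB = 0.55)),
    fleet("netters12", 3800, 7000,
          list(COD_KA = cd(350), COD_WB = cd(840), SPR_KAWB = cd(70),
               NEP_KAWB = cd(42)),
          list(fuel_per_day = 120, variable_per_day = 150, crew_share = 0.35,
               fixed_per_year = 2.5e5, capital_per_year = 1.2e5),
          c(COD_KA = 0.25, COD_WB = 0.35, SPR_KAWB = 0.01, NEP_KAWB = 0.10),
          c(KA = 0.40, WB = 0.60))),
    class = "bs_fleets")
}

#' Scale stock biomasses by ecosystem comparison indices
#'
#' `TSB' = TSB * (1 + index / 100)` with the index taken from the
#' area-matched stock index of a scenario comparison (or supplied directly as
#' a named vector of percent changes).
#'
#' @param stocks a stock table (see [default_stocks()]).
#' @param comparison a `bs_comparison` from [compare()], or a named numeric
#'   vector of percent indices keyed by stock_id.
#' @return The stock table with scaled TSB.
#' @export
scale_stocks <- function(stocks, comparison) {
  if (inherits(comparison, "bs_comparison")) {
    si <- comparison$stock_indices
    key <- paste(si$group, si$area, sep = "_")
    idx <- stats::setNames(si$index_plain, key)
    lookup <- paste(stocks$group, stocks$area, sep = "_")
    vals <- idx[lookup]
  } else {
    vals <- comparison[stocks$stock_id]
  }
  if (anyNA(vals)) bs_stop(sprintf(
    "no comparison index for stock(s): %s",
    paste(stocks$stock_id[is.na(vals)], collapse = ",")),
    "baltisim_lookup_error")
  stocks$TSB <- stocks$TSB * (1 + unname(vals) / 100)
  stocks
}

#' Cobb-Douglas catch production
#'
#' `C = A * (E / E_ref)^alpha_E * (B / B_ref)^beta_B` in tons per year, with
#' reference effort and biomass from the base-year configuration. Zero effort
#' yields zero catch.
#'
#' @param A intercept, tons at reference conditions.
#' @param effort,effort_ref fishing effort, days per year.
#' @param TSB,TSB_ref stock biomass, tons.
#' @param alpha_E,beta_B output elasticities.
#' @return Catch in tons.
#' @export
catch_production <- function(A, effort, effort_ref, TSB, TSB_ref,
                             alpha_E = 1, beta_B = 1) {
  bs_validate(effort >= 0, "negative effort")
  if (effort == 0) return(0)
  A * (effort / effort_ref)^alpha_E * (TSB / TSB_ref)^beta_B
}

# unconstrained landings matrix [fleet, stock] at given efforts
landings_matrix <- function(fleets, stocks, efforts, tsb_ref) {
  L <- matrix(0, length(fleets), nrow(stocks),
              dimnames = list(vapply(fleets, `[[`, "", "fleet_id"),
                              stocks$stock_id))
  for (i in seq_along(fleets)) {
    fl <- fleets[[i]]
    for (s in seq_len(nrow(stocks))) {
      cdp <- fl$cobb_douglas[[stocks$stock_id[s]]]
      if (is.null(cdp)) next
      L[i, s] <- catch_production(cdp$A, efforts[i], fl$effort_ref,
                                  stocks$TSB[s], tsb_ref[s],
                                  cdp$alpha_E, cdp$beta_B)
    }
  }
  L
}

#' Apply TAC constraints with the choke rule
#'
#' Each fleet's landings of a stock are capped at its quota share of the TAC.
#' When any cap binds, the fleet's effort is scaled down by the single factor
#' that brings the binding (choke) stock exactly to its quota, which scales
#' the fleet's landings of every stock.
#'
#' @param fleets a `bs_fleets`.
#' @param stocks stock table.
#' @param efforts numeric vector of fleet efforts (days).
#' @param tsb_ref reference biomasses (defaults to current TSB).
#' @return list(landings, efforts, choke) with the constrained landings
#'   matrix, scaled efforts and logical choke flags per fleet.
#' @export
apply_tac <- function(fleets, stocks, efforts = NULL, tsb_ref = NULL) {
  if (is.null(efforts)) efforts <- vapply(fleets, `[[`, 0, "effort")
  if (is.null(tsb_ref))
    tsb_ref <- if (!is.null(stocks$TSB_ref)) stocks$TSB_ref else stocks$TSB
  L <- landings_matrix(fleets, stocks, efforts, tsb_ref)
  choke <- logical(length(fleets))
  for (i in seq_along(fleets)) {
    fl <- fleets[[i]]
    caps <- fl$quota_share[stocks$stock_id] * stocks$TAC
    active <- which(L[i, ] > 0 & is.finite(caps))
    if (!length(active)) next
    ratio <- caps[active] / L[i, active]
    r <- min(ratio)
    if (r < 1) {
      choke[i] <- TRUE
      # effort scale solving max_s landings_s(t E) / cap_s = 1
      alphas <- vapply(active, function(s) {
        cdp <- fl$cobb_douglas[[stocks$stock_id[s]]]
        if (is.null(cdp)) 1 else cdp$alpha_E
      }, 0)
      t_scale <- min(pmin(ratio, 1)^(1 / alphas))
      efforts[i] <- efforts[i] * t_scale
      L[i, ] <- landings_matrix(fleets[i], stocks, efforts[i], tsb_ref)
    }
  }
  list(landings = L, efforts = efforts, choke = choke)
}

#' One fleet-year of economic accounting
#'
#' `revenue = sum(price * landings)`; fuel and other variable costs scale
#' with effort, crew cost is a share of revenue, fixed and capital costs are
#' annual constants; `profit = revenue - sum(costs)` exactly. Every line item
#' is split over areas by the fleet's activity keys.
#'
#' @param fleet one fleet definition.
#' @param landings named vector of tons per stock.
#' @param prices named vector of EUR per ton per stock.
#' @param effort days fished.
#' @return list(revenue, fuel, variable, crew, fixed, capital, profit,
#'   by_area).
#' @export
fleet_economics <- function(fleet, landings, prices, effort) {
  revenue <- sum(prices[names(landings)] * landings)
  fuel <- fleet$costs$fuel_per_day * effort
  variable <- fleet$costs$variable_per_day * effort
  crew <- fleet$costs$crew_share * revenue
  fixed <- fleet$costs$fixed_per_year
  capital <- fleet$costs$capital_per_year
  profit <- revenue - (fuel + variable + crew + fixed + capital)
  by_area <- lapply(fleet$area_keys, function(k)
    c(revenue = k * revenue, profit = k * profit))
  list(revenue = revenue, fuel = fuel, variable = variable, crew = crew,
       fixed = fixed, capital = capital, profit = profit, by_area = by_area)
}

#' Project fleet economics and net present value
#'
#' Annual loop over the horizon: a bounded profit-following behavior step
#' adjusts each fleet's effort
#' (`E' = E * (1 + lambda * sign(profit) * min(|profit|/revenue, cap))`,
#' clamped to `[0, max_effort]`), then catch production, TAC/choke
#' constraints and cost accounting. Stock biomasses and recruitment stay
#' constant (the ecosystem signal enters through pre-scaled TSB). NPV
#' discounts profits to the first year.
#'
#' @param fleets a `bs_fleets`.
#' @param stocks stock table (possibly scaled by [scale_stocks()]).
#' @param years projection years (default 2012:2037).
#' @param discount annual discount rate (default 0.04).
#' @param lambda behavior step gain (default 0.1; 0 disables adaptation).
#' @param step_cap bound on the relative effort adjustment per year.
#' @return A `bs_econ` list: `annual` data.frame (fleet, year, effort,
#'   revenue, cost lines, profit, choke), `npv_total`, `npv_by_area`
#'   (million EUR), `landings` array.
#' @export
project_npv <- function(fleets, stocks, years = 2012:2037, discount = 0.04,
                        lambda = 0.1, step_cap = 0.5) {
  bs_validate(length(years) >= 1, "horizon must cover at least one year")
  bs_validate(discount >= 0, "discount rate must be >= 0")
  efforts <- vapply(fleets, `[[`, 0, "effort")
  max_eff <- vapply(fleets, `[[`, 0, "max_effort")
  ids <- vapply(fleets, `[[`, "", "fleet_id")
  prices <- stats::setNames(stocks$price, stocks$stock_id)
  tsb_ref <- if (!is.null(stocks$TSB_ref)) stocks$TSB_ref else stocks$TSB
  rows <- list()
  land <- array(0, c(length(fleets), nrow(stocks), length(years)),
                dimnames = list(ids, stocks$stock_id, years))
  npv <- 0
  npv_area <- c(KA = 0, WB = 0)
  last_profit <- rep(NA_real_, length(fleets))
  last_revenue <- rep(NA_real_, length(fleets))
  for (t in seq_along(years)) {
    if (t > 1 && lambda > 0) {
      adj <- ifelse(last_revenue > 0,
                    lambda * sign(last_profit) *
                      pmin(abs(last_profit) / last_revenue, step_cap), 0)
      efforts <- pmin(pmax(efforts * (1 + adj), 0), max_eff)
    }
    tac <- apply_tac(fleets, stocks, efforts, tsb_ref)
    disc <- (1 + discount)^(years[t] - years[1])
    for (i in seq_along(fleets)) {
      ec <- fleet_economics(fleets[[i]], tac$landings[i, ], prices,
                            tac$efforts[i])
      rows[[length(rows) + 1]] <- data.frame(
        fleet = ids[i], year = years[t], effort = tac$efforts[i],
        revenue = ec$revenue, fuel = ec$fuel, variable = ec$variable,
        crew = ec$crew, fixed = ec$fixed, capital = ec$capital,
        profit = ec$profit, choke = tac$choke[i])
      npv <- npv + ec$profit / disc
      for (an in names(npv_area))
        npv_area[an] <- npv_area[an] +
          fleets[[i]]$area_keys[[an]] * ec$profit / disc
      last_profit[i] <- ec$profit
      last_revenue[i] <- ec$revenue
    }
    land[, , t] <- tac$landings
    # note: behavior uses realized (possibly choke-scaled) effort as the base
    efforts <- tac$efforts
  }
  structure(list(annual = do.call(rbind, rows),
                 npv_total = npv / 1e6, npv_by_area = npv_area / 1e6,
                 landings = land),
            class = "bs_econ")
}
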