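test_that("stock scaling applies comparison indices multiplicatively", {
  st <- default_stocks()
  idx <- c(COD_KA = 0, COD_WB = 100, SPR_KAWB = -20.97, NEP_KAWB = 0)
  st2 <- scale_stocks(st, idx)
  expect_equal(st2$TSB[st2$stock_id == "COD_KA"],
               st$TSB[st$stock_id == "COD_KA"])
  expect_equal(st2$TSB[st2$stock_id == "COD_WB"],
               2 * st$TSB[st$stock_id == "COD_WB"])
  expect_equal(st2$TSB[st2$stock_id == "SPR_KAWB"],
               st$TSB[st$stock_id == "SPR_KAWB"] * (1 - 0.2097))
  # an index of -20.97 on 1000 t leaves 790.3 t
  st$TSB[4] <- 1000
  st3 <- scale_stocks(st, c(COD_KA = 0, COD_WB = 0, SPR_KAWB = 0,
                            NEP_KAWB = -20.97))
  expect_equal(st3$TSB[4], 790.3, tolerance = 1e-9)
  expect_error(scale_stocks(st, c(COD_KA = 0)),
               class = "baltisim_lookup_error")
})

test_that("Cobb-Douglas production has its normalization and homogeneity", {
  expect_equal(catch_production(500, 0, 1000, 5e4, 5e4), 0)
  expect_equal(catch_production(500, 1000, 1000, 5e4, 5e4), 500)
  expect_equal(catch_production(500, 2000, 1000, 5e4, 5e4), 1000)
  expect_equal(catch_production(500, 1000, 1000, 2.5e4, 5e4, beta_B = 1), 250)
  expect_error(catch_production(500, -1, 1000, 1, 1),
               class = "baltisim_validation_error")
})

test_that("the choke rule brings the binding stock exactly to quota", {
  # hand-solved one-fleet two-stock case, alpha_E = 1:
  # unconstrained landings (100, 400); quota caps (200, 200)
  # -> stock B binds at ratio 0.5, effort halves, landings (50, 200)
  stocks <- data.frame(stock_id = c("A", "B"), group = NA, area = NA,
                       TSB = c(1e4, 1e4), F = 0, M = 0,
                       TAC = c(400, 400), price = c(10, 10))
  fleet <- list(list(
    fleet_id = "f1", effort = 100, max_effort = 200, effort_ref = 100,
    cobb_douglas = list(A = list(A = 100, alpha_E = 1, beta_B = 1),
                        B = list(A = 400, alpha_E = 1, beta_B = 1)),
    costs = list(fuel_per_day = 1, variable_per_day = 1, crew_share = 0.1,
                 fixed_per_year = 10, capital_per_year = 10),
    quota_share = c(A = 0.5, B = 0.5),
    area_keys = c(KA = 0.6, WB = 0.4)))
  class(fleet) <- "bs_fleets"
  out <- apply_tac(fleet, stocks)
  expect_true(out$choke[1])
  expect_equal(out$efforts[1], 50)
  expect_equal(unname(out$landings[1, ]), c(50, 200), tolerance = 1e-9)
  # ample quotas leave landings unchanged with no flags
  stocks$TAC <- c(1e6, 1e6)
  out2 <- apply_tac(fleet, stocks)
  expect_false(out2$choke[1])
  expect_equal(unname(out2$landings[1, ]), c(100, 400))
  # a zero quota for a caught stock drives effort to zero
  stocks$TAC <- c(1e6, 0)
  out3 <- apply_tac(fleet, stocks)
  expect_equal(out3$efforts[1], 0)
})

test_that("fleet-year accounting closes exactly and splits by area", {
  fl <- default_fleets()[[1]]
  landings <- c(COD_KA = 100, COD_WB = 50, SPR_KAWB = 1000, NEP_KAWB = 20)
  prices <- stats::setNames(default_stocks()$price,
                            default_stocks()$stock_id)
  ec <- fleet_economics(fl, landings, prices, effort = 2000)
  expect_equal(ec$profit,
               ec$revenue - (ec$fuel + ec$variable + ec$crew + ec$fixed +
                               ec$capital), tolerance = 1e-9)
  expect_equal(ec$crew, fl$costs$crew_share * ec$revenue)
  expect_equal(ec$by_area$KA[["revenue"]] + ec$by_area$WB[["revenue"]],
               ec$revenue, tolerance = 1e-9)
  # zero effort: revenue zero, profit is minus the standing costs
  ec0 <- fleet_economics(fl, landings * 0, prices, effort = 0)
  expect_equal(ec0$revenue, 0)
  expect_equal(ec0$profit, -(fl$costs$fixed_per_year +
                               fl$costs$capital_per_year))
})

test_that("NPV matches the annuity closed form and r = 0 sums profits", {
  # a fleet that never fishes has constant negative profit
  fl <- default_fleets()[1]
  fl[[1]]$effort <- 0; fl[[1]]$effort_ref <- 1
  stocks <- default_stocks()
  out <- project_npv(fl, stocks, years = 2012:2037, discount = 0.04,
                     lambda = 0)
  P <- -(fl[[1]]$costs$fixed_per_year + fl[[1]]$costs$capital_per_year)
  n <- 26; r <- 0.04
  annuity <- P * (1 - (1 + r)^(-n)) / r * (1 + r)
  expect_equal(out$npv_total * 1e6, annuity, tolerance = 1e-9 * abs(annuity))
  out0 <- project_npv(fl, stocks, years = 2012:2037, discount = 0,
                      lambda = 0)
  expect_equal(out0$npv_total * 1e6, P * n, tolerance = 1e-9)
  # lambda = 0 with constant stocks: identical annual records every year
  outc <- project_npv(default_fleets(), stocks, years = 2012:2016,
                      discount = 0.04, lambda = 0)
  a <- outc$annual
  for (f in unique(a$fleet)) {
    pf <- a$profit[a$fleet == f]
    expect_true(all(abs(pf - pf[1]) < 1e-6 * (1 + abs(pf[1]))))
  }
})

test_that("economic monotonicity: weaker stocks never raise pre-TAC landings", {
  fl <- default_fleets()
  st <- default_stocks()
  effort <- vapply(fl, `[[`, 0, "effort")
  L_base <- baltisim:::landings_matrix(fl, st, effort, st$TSB)
  st2 <- st; st2$TSB[3] <- st2$TSB[3] * 0.7
  L_low <- baltisim:::landings_matrix(fl, st2, effort, st$TSB)
  expect_true(all(L_low[, 3] <= L_base[, 3]))
  expect_equal(L_low[, -3], L_base[, -3])
})
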