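test_that("the multi-prey disc equation has its two limiting regimes", {
  # committed worked case: C=0.1, g=0.5, a=1, density 10 -> 1/3 per day
  r <- holling_intake(clearance = 0.1, max_intake = 0.5, a = 1, rho = 10)
  expect_equal(r, 1 / 3, tolerance = 1e-12)
  # saturation: total intake approaches g as prey grow dense
  r_inf <- holling_intake(0.1, 0.5, a = c(1, 1), rho = c(1e9, 1e9))
  expect_equal(sum(r_inf), 0.5, tolerance = 1e-6)
  # linear clearance regime within 1% when C a rho / g < 0.01
  rho <- 0.04   # C a rho / g = 0.008
  r_lin <- holling_intake(0.1, 0.5, 1, rho)
  expect_equal(r_lin, 0.1 * rho, tolerance = 0.01)
  # independent scalar implementation of the same functional form
  ind <- function(C, g, a, rho) (C * a * rho) / (1 + sum(C * a * rho) / g)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(3); rho <- runif(3, 0, 50)
    expect_equal(holling_intake(0.07, 0.4, a, rho), ind(0.07, 0.4, a, rho),
                 tolerance = 1e-12)
  }
})

test_that("available prey composes availability, gape, refuge and overlap", {
  expect_equal(available_prey(a = 0, B_prey = 100), 0)
  expect_equal(available_prey(1, 100, prey_weight = 10, pred_weight = 10,
                              gape = c(1e-3, 0.1)), 0)   # outside window
  expect_equal(available_prey(1, 100, prey_weight = 1, pred_weight = 100,
                              gape = c(1e-3, 0.1)), 100) # identity case
  expect_equal(available_prey(0.5, 100, refuge_frac = 0.2, overlap = 0.5),
               0.5 * 0.5 * 0.8 * 100)
})

test_that("consume caps at available prey and conserves mass", {
  out <- consume(pred_biomass = 1e9, clearance = 0.1, max_intake = 0.5,
                 a = c(1, 1), B_eff = c(10, 20), volume = 1, dt = 1)
  expect_true(all(out$intake <= c(10, 20) + 1e-12))
  out2 <- consume(1, 0.1, 0.5, 1, B_eff = 10, volume = 1)
  expect_equal(out2$intake, 1 / 3, tolerance = 1e-9)
  expect_error(consume(-1, 0.1, 0.5, 1, 10, 1),
               class = "baltisim_validation_error")
})

test_that("growth splits intake exactly into growth, detritus and ammonium", {
  g1 <- grow(10, assim = 1)
  expect_equal(g1$growth, 10); expect_equal(g1$detritus + g1$nh4, 0)
  g2 <- grow(10, assim = 0.1, egestion_frac = 0.6)
  expect_equal(g2$growth, 1)
  expect_equal(g2$detritus, 9 * 0.6)
  expect_equal(g2$growth + g2$detritus + g2$nh4, 10, tolerance = 1e-12)
  expect_error(grow(1, assim = 0), class = "baltisim_validation_error")
})

test_that("Beverton-Holt recruitment has its asymptote and half-saturation", {
  r_inf <- recruit(S = 1e12, alpha = 1000, beta = 10)
  expect_equal(r_inf$recruits, 1000, tolerance = 1e-6)
  r_half <- recruit(S = 10, alpha = 1000, beta = 10)
  expect_equal(r_half$recruits, 500, tolerance = 1e-12)
  # environmental ramps multiply; below the lower anchor the scalar is zero
  ramps <- list(O2 = c(2 * 1429, 3 * 1429))
  r0 <- recruit(10, 1000, 10, env = list(O2 = 1.9 * 1429), ramps = ramps)
  expect_equal(r0$recruits, 0)
  rmid <- recruit(10, 1000, 10, env = list(O2 = 2.5 * 1429), ramps = ramps)
  expect_equal(rmid$phi, 0.5, tolerance = 1e-9)
  expect_error(recruit(10, 1000, beta = 0),
               class = "baltisim_validation_error")
})

test_that("survivorship equilibrium matches the analytic age structure", {
  # constant recruitment and mortality: N_a = R exp(-sum_{j<a} Z_j)
  R <- 1000
  Z <- c(0.5, 0.4, 0.6, 0.3, 0.7)
  v <- list(numbers = rep(0, 6), weight_s = rep(1, 6), weight_r = rep(1, 6))
  for (yr in 1:60) {
    for (d in 1:365) v$numbers <- survive(v$numbers, c(Z, Z[5]), 1)
    v <- age_cohorts(v, recruit_weight = 1, reserve_frac = 0.5)
    v$numbers[1] <- R
  }
  expected <- R * exp(-cumsum(Z[1:4]))
  expect_equal(v$numbers[2:5], expected, tolerance = 0.01)
  expect_true(all(diff(v$numbers[1:5]) < 0) || Z[1] == 0)
})

test_that("ageing shifts cohorts and accumulates the plus group exactly", {
  v <- list(numbers = c(10, 20, 30, 40), weight_s = c(1, 2, 3, 4),
            weight_r = c(1, 2, 3, 4))
  v2 <- age_cohorts(v, recruit_weight = 2, reserve_frac = 0.5)
  expect_equal(v2$numbers, c(0, 10, 20, 70))
  # plus-group weight is the biomass-weighted mean
  expect_equal(v2$weight_s[4], (30 * 3 + 40 * 4) / 70)
  # ageing itself conserves biomass exactly (cohort 1 is emptied, the
  # departing cohort-1 fish carry their weights up)
  expect_equal(sum(v2$numbers * (v2$weight_s + v2$weight_r)),
               sum(v$numbers * (v$weight_s + v$weight_r)))
})

test_that("redistribution conserves totals and handles anoxic exclusion", {
  m <- c(0.2, 0.3, 0.5)
  expect_equal(sum(redistribute(m)), 1, tolerance = 1e-12)
  r <- redistribute(m, admissible = c(TRUE, FALSE, TRUE))
  expect_equal(r[2], 0)
  expect_equal(sum(r), 1, tolerance = 1e-12)
  expect_equal(r[3] / r[1], m[3] / m[1], tolerance = 1e-12)
  expect_equal(sum(redistribute(m, rep(FALSE, 3))), 0)
})
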