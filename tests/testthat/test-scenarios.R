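test_that("the shipped catalog reproduces the printed scenario settings", {
  g <- example_geometry("mini8")
  sc <- build_scenarios(g)
  expect_length(sc, 10)
  # halved-F scenarios derive from the configured baselines
  expect_equal(sc$scenario6$F_overrides$FCD$adult, 0.32 / 2)
  expect_equal(sc$scenario7$F_overrides$FSR$adult, 0.07 / 2)
  # printed F values used verbatim for the increase scenarios
  expect_equal(sc$scenario8$F_overrides$FCD$adult, 0.64)
  expect_equal(sc$scenario9$F_overrides$FSR$adult, 0.14)
  expect_equal(sc$scenario10$F_overrides$FCD$adult, 1.2)
  expect_equal(sc$scenario10$F_overrides$FSR$adult, 0.6)
  # juvenile override defaults to half the new adult value
  expect_equal(sc$scenario6$F_overrides$FCD$juvenile, 0.08)
  # pan-Baltic reduction covers every dynamic box at 0.67
  m5 <- sc$scenario5$load_multiplier
  expect_setequal(as.integer(names(m5)), g$boxes$box_id[g$dynamic])
  expect_true(all(abs(m5 - 0.67) < 1e-12))
  # status quo carries no interventions
  expect_length(sc$status_quo$load_multiplier, 0)
  expect_length(sc$status_quo$F_overrides, 0)
  # per-box reductions of the Danish scenario
  expect_equal(unname(sc$scenario2$load_multiplier[c("1", "2", "4")]),
               1 - c(12, 33, 24) / 100)
})

test_that("scenario validation rejects malformed specifications", {
  expect_error(bs_scenario("x", load_multiplier = c(`1` = 1.2)),
               class = "baltisim_validation_error")
  expect_error(bs_scenario("x", change_year = 70, horizon_years = 60),
               class = "baltisim_validation_error")
  # juvenile default rule
  s <- bs_scenario("x", F_overrides = list(FCD = list(adult = 0.5)))
  expect_equal(s$F_overrides$FCD$juvenile, 0.25)
})

test_that("terminal averaging reduces to the expected arithmetic", {
  fake <- structure(list(
    years = 10, scenario = NULL,
    group_names = "G",
    annual_biomass = array(1:10, c(10, 1, 1), dimnames = list(NULL, "G"))),
    class = "bs_run")
  expect_equal(unname(terminal_average(fake, 1)["G", 1]), 10)
  expect_equal(unname(terminal_average(fake, 5)["G", 1]), 8)  # T - 2 for a ramp
  const <- fake
  const$annual_biomass[] <- 3.5
  expect_equal(unname(terminal_average(const, 4)["G", 1]), 3.5)
  expect_error(terminal_average(fake, 0), class = "baltisim_validation_error")
})

test_that("comparing a run against itself is identically zero", {
  fake <- structure(list(
    years = 6, scenario = NULL, group_names = c("A", "B"),
    geometry = example_geometry("mini8"),
    annual_biomass = array(runif(6 * 2 * 8, 1, 2), c(6, 2, 8),
                           dimnames = list(NULL, c("A", "B"))),
    bottom_o2 = matrix(runif(48), 6, 8),
    maps = list()), class = "bs_run")
  cmp <- compare(fake, fake, window = 3)
  expect_true(all(cmp$groups$pct_change == 0))
  expect_true(all(cmp$bottom_o2$delta == 0))
  # doubling one group doubles its percent change to +100
  dbl <- fake
  dbl$annual_biomass[, "A", ] <- 2 * fake$annual_biomass[, "A", ]
  cmp2 <- compare(dbl, fake, window = 3)
  expect_equal(cmp2$groups$pct_change[cmp2$groups$group == "A"], 100,
               tolerance = 1e-9)
  # zero baseline is flagged undefined, never infinite
  z <- fake
  z$annual_biomass[, "B", ] <- 0
  cmp3 <- compare(fake, z, window = 3)
  expect_true(cmp3$groups$undefined[cmp3$groups$group == "B"])
  expect_false(any(is.infinite(cmp3$groups$pct_change), na.rm = TRUE))
})

test_that("migration-aware and plain stock indices agree for static maps", {
  g <- example_geometry("mini8")
  mkrun <- function(scale) {
    ab <- array(0, c(6, 1, 8), dimnames = list(NULL, "FCD"))
    # biomass proportional to a quarter-invariant map
    map <- array(0, c(2, 4, 8), dimnames = list(c("juv", "adult"), NULL, NULL))
    shares <- c(0, 0.1, 0.2, 0.3, 0.1, 0.1, 0.1, 0.1)
    for (stg in 1:2) for (q in 1:4) map[stg, q, ] <- shares
    for (y in 1:6) ab[y, 1, ] <- scale * shares
    structure(list(years = 6, scenario = NULL, group_names = "FCD",
                   geometry = g, annual_biomass = ab,
                   bottom_o2 = matrix(0, 6, 8),
                   maps = list(FCD = map)), class = "bs_run")
  }
  cmp <- compare(mkrun(120), mkrun(100), window = 3)
  si <- cmp$stock_indices
  expect_equal(si$index_plain, si$index_migration, tolerance = 1e-9)
  expect_equal(si$index_plain, rep(20, nrow(si)), tolerance = 1e-9)
})
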