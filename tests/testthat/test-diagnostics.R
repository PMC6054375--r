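test_that("equilibrium detection flags drift and tolerates seasonal cycles", {
  const <- rep(5, 30)
  eq <- detect_equilibrium(const)
  expect_true(eq$flag); expect_equal(eq$drift, 0)
  growing <- 100 * 1.01^(1:30)          # ~10% per decade
  expect_false(detect_equilibrium(growing)$flag)
  # annual means of a pure seasonal cycle are constant
  seasonal <- rep(7, 25)
  expect_true(detect_equilibrium(seasonal)$flag)
  expect_true(is.na(detect_equilibrium(rep(0, 30))$flag))
})

test_that("biomass factors are computed and band-flagged inclusively", {
  fake <- structure(list(
    years = 10, scenario = NULL, group_names = c("A", "B", "C"),
    annual_biomass = array(0, c(10, 3, 2),
                           dimnames = list(NULL, c("A", "B", "C"))),
    initial = list(biomass = c(A = 10, B = 10, C = 10))),
    class = "bs_run")
  fake$annual_biomass[, "A", ] <- 5      # per-box; total 10 -> factor 1
  fake$annual_biomass[, "B", ] <- 13.6   # factor 2.72 -> flagged
  fake$annual_biomass[, "C", ] <- 2.5    # factor 0.5, boundary inclusive
  bf <- biomass_factor(fake)
  expect_equal(bf$factor, c(1, 2.72, 0.5))
  expect_equal(bf$flagged, c(FALSE, TRUE, FALSE))
})

test_that("diet composition is the normalized feeding ledger", {
  diet <- array(0, c(6, 2, 3),
                dimnames = list(NULL, c("FCD_adult", "FCD_juv"),
                                c("FSR", "HER", "OTH")))
  diet[2:6, "FCD_adult", ] <- rep(c(80, 15, 5), each = 5)
  fake <- structure(list(years = 6, diet = diet), class = "bs_run")
  dc <- diet_composition(fake, "FCD_adult", last_n_years = 5)
  expect_equal(unname(dc), c(0.80, 0.15, 0.05))
  expect_equal(sum(dc), 1, tolerance = 1e-9)
  # a stage that consumed nothing is NA-flagged, not NaN
  dj <- diet_composition(fake, "FCD_juv")
  expect_true(all(is.na(dj)))
  all_st <- diet_composition(fake)
  expect_equal(unname(all_st["FCD_adult", ]), c(0.80, 0.15, 0.05))
})

test_that("demography report flags monotone and inverted age pyramids", {
  mk <- function(n) structure(list(
    years = 10, numbers = list(G = matrix(rep(n, each = 10), 10))),
    class = "bs_run")
  survivorship <- 1000 * exp(-0.5 * (0:5))
  expect_true(demography_report(mk(survivorship), "G")$monotone)
  expect_false(demography_report(mk(rev(survivorship)), "G")$monotone)
  expect_true(demography_report(mk(c(10)), "G")$monotone)
  # plus-group accumulation is exempt from the monotonicity requirement
  plus <- c(1000, 600, 300, 900)
  expect_true(demography_report(mk(plus), "G")$monotone)
  inverted_young <- c(600, 1000, 300, 200)
  expect_false(demography_report(mk(inverted_young), "G")$monotone)
})

test_that("persistence flags respect migration-driven seasonal absence", {
  g <- example_geometry("mini8")
  nb <- nrow(g$boxes)
  ab <- array(1, c(6, 2, nb), dimnames = list(NULL, c("RES", "MIG")))
  maps <- list(
    RES = array(1 / 7, c(2, 4, nb), dimnames = list(c("juv", "adult"))),
    MIG = array(0, c(2, 4, nb), dimnames = list(c("juv", "adult"))))
  maps$RES[, , 1] <- 0
  # migratory group never uses the last box in any quarter
  for (q in 1:4) for (stg in 1:2)
    maps$MIG[stg, q, ] <- c(0, rep(1 / 6, 6), 0)
  ab[2:6, "RES", 4] <- 0   # present in year 1, then lost in box 3: flagged
  ab[, "MIG", 8] <- 0      # migrant zero where its map share is zero: ok
  ab[, "RES", 2] <- 0      # never occupied (e.g. always avoided): not flagged
  fake <- structure(list(
    years = 6, geometry = g, group_names = c("RES", "MIG"),
    annual_biomass = ab, maps = maps,
    initial = list(biomass = c(RES = 10, MIG = 10))), class = "bs_run")
  fl <- persistence_check(fake)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$group, "RES"); expect_equal(fl$box, 3)
})
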