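test_that("physics forcing is a pure function of seed with balanced exchange", {
  g <- example_geometry("mini8")
  f1 <- generate_physics(g, seed = 7)
  f2 <- generate_physics(g, seed = 7)
  expect_identical(f1$exchange, f2$exchange)
  expect_identical(f1$temperature, f2$temperature)
  f3 <- generate_physics(g, seed = 8)
  expect_false(identical(f1$exchange, f3$exchange))

  # per dynamic box and layer, signed fluxes sum to zero at every step
  plan <- baltisim:::make_transport_plan(g)
  for (s in c(1L, 180L, 365L, 730L)) {
    q <- f1$exchange[s, , ][cbind(plan$af$face, plan$af$layer)]
    div <- numeric(length(plan$vol))
    for (k in seq_along(q)) {
      div[plan$af$rcell[k]] <- div[plan$af$rcell[k]] + q[k]
      div[plan$af$lcell[k]] <- div[plan$af$lcell[k]] - q[k]
    }
    dyn_cells <- which(plan$realized &
                         (((seq_along(plan$vol) - 1) %% plan$nb) + 1) %in%
                           g$dynamic)
    expect_lt(max(abs(div[dyn_cells])) / max(abs(q)), 1e-6)
  }
})

test_that("temperature and salinity follow the configured structure", {
  g <- example_geometry("mini8")
  f <- generate_physics(g, seed = 1)
  coastal <- which(f$coastal & g$boxes$kind == "dynamic")[1]
  expect_lte(min(f$temperature[, coastal, 1]),
             default_physics_params()$t_min)
  # surface salinity declines monotonically along the box axis
  surf_sal <- f$salinity[1, , 1]
  expect_true(all(diff(surf_sal) < 0))
  # negative-salinity parameterizations are rejected
  p <- default_physics_params()
  p$sal_axis_drop <- 50
  expect_error(generate_physics(g, p, seed = 1),
               class = "baltisim_validation_error")
})

test_that("forcing is exactly annually periodic in the run loop", {
  f <- generate_physics(example_geometry("mini8"), seed = 1)
  # one stored year is indexed cyclically, so periodicity is structural
  expect_equal(dim(f$exchange)[1], 730)
  expect_equal(f$dt_hours, 12)
})

test_that("river load accounting respects retention and spill redirection", {
  g <- example_geometry("mini8")
  l <- generate_loads(g, seed = 3)
  expect_true(all(l$retention >= 0 & l$retention <= 1))
  expect_false(any(l$box_id %in% g$boxes$box_id[g$boundary]))
  eff <- effective_daily_loads(l, g)
  expect_equal(sum(eff) * 365 / 1e9,
               sum(l$annual_total_tN * (1 - l$retention)),
               tolerance = 1e-9)
  # worked example: 36,500 t in one box, no retention, pure DIN
  l1 <- l[1, ]
  l1$annual_total_tN <- 36500
  l1$retention <- 0; l1$din_fraction <- 1
  l1$offshore_spill_fraction <- 0
  e1 <- effective_daily_loads(l1, g)
  expect_equal(sum(e1[, "DIN"]) / 1e9, 100, tolerance = 1e-12)
  # full retention removes the load
  l1$retention <- 1
  expect_equal(sum(effective_daily_loads(l1, g)), 0)
  # spill split 70/30 between source and paired offshore box
  l2 <- l[1, ]
  l2$offshore_spill_fraction <- 0.3
  e2 <- effective_daily_loads(l2, g)
  src <- l2$box_id + 1L; tgt <- l2$spill_target + 1L
  expect_equal(sum(e2[src, ]) / (sum(e2[src, ]) + sum(e2[tgt, ])), 0.7,
               tolerance = 1e-9)
})

test_that("atmospheric deposition is uniform, linear in area, and converted", {
  g <- example_geometry("mini8")
  dep <- deposition_flux(g, 0.15)
  # 0.15 mmol m-2 day-1 over 1e9 m2 is 2.1e9 mg N per day
  expect_equal(dep[1] / g$boxes$area[1] * 1e9, 2.1e9, tolerance = 1e-9)
  expect_equal(deposition_flux(g, 0), rep(0, 8))
  g2 <- g; g2$boxes$area <- g$boxes$area * 2
  expect_equal(deposition_flux(g2, 0.15), 2 * dep)
})

test_that("initial conditions honour targets, habitat and the detritus rule", {
  g <- example_geometry("mini8")
  gr <- default_groups()
  ic <- generate_initial_conditions(g, gr, seed = 5)
  cnst <- baltisim_constants
  dyn <- g$dynamic
  # per-group totals match the configured targets
  for (tr in c("PS", "PL", "ZM")) {
    tgt <- if (tr == "ZM") gr$pools$ZM$target_biomass else
      gr$producers[[tr]]$target_biomass
    got <- sum(ic$tracers$conc[dyn, , tr] * g$volume[dyn, ], na.rm = TRUE) /
      cnst$mg_n_per_ton
    expect_equal(got, tgt, tolerance = 1e-6)
  }
  for (p in c("BD", "NE"))
    expect_equal(sum(ic$pools[p, ]) / cnst$mg_n_per_ton,
                 gr$pools[[p]]$target_biomass, tolerance = 1e-6)
  for (v in names(gr$verts)) {
    got <- sum(ic$verts[[v]]$numbers *
                 (ic$verts[[v]]$weight_s + ic$verts[[v]]$weight_r)) /
      cnst$mg_n_per_ton
    expect_equal(got, gr$verts[[v]]$target_biomass, tolerance = 1e-6)
    for (stg in 1:2) for (q in 1:4)
      expect_equal(sum(ic$maps[[v]][stg, q, ]), 1, tolerance = 1e-9)
  }
  # water-column detritus starts very low relative to plankton stock
  plank <- sum(ic$tracers$conc[dyn, , "PS"] * g$volume[dyn, ],
               ic$tracers$conc[dyn, , "PL"] * g$volume[dyn, ], na.rm = TRUE)
  det <- sum(ic$tracers$conc[dyn, , "DL"] * g$volume[dyn, ],
             ic$tracers$conc[dyn, , "DR"] * g$volume[dyn, ], na.rm = TRUE)
  expect_lt(det / plank, 0.2)
  # determinism and seed sensitivity
  ic2 <- generate_initial_conditions(g, gr, seed = 5)
  expect_identical(ic$pools, ic2$pools)
  ic3 <- generate_initial_conditions(g, gr, seed = 6)
  expect_false(identical(ic$pools, ic3$pools))
  expect_equal(sum(ic3$pools["BD", ]), sum(ic$pools["BD", ]),
               tolerance = 1e-9)
})

test_that("benthos is placed only on admissible habitat", {
  g <- example_geometry("mini8")
  gr <- default_groups()
  # a filter feeder restricted to bedrock, present only in one box
  g$boxes[, c("bedrock", "sand", "mud", "manmade")] <- 0
  g$boxes$mud <- 1
  g$boxes$mud[4] <- 0; g$boxes$bedrock[4] <- 1
  g <- validate_geometry(g)
  gr$pools$NE$habitat_affinity <- c(bedrock = 1, sand = 0, mud = 0,
                                    manmade = 0)
  ic <- generate_initial_conditions(g, gr, seed = 1)
  expect_true(all(ic$pools["NE", -4] == 0))
  expect_gt(ic$pools["NE", 4], 0)
  # no admissible habitat anywhere is an error
  gr$pools$NE$habitat_affinity <- c(bedrock = 0, sand = 0, mud = 0,
                                    manmade = 1)
  expect_error(generate_initial_conditions(g, gr, seed = 1),
               class = "baltisim_validation_error")
})
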