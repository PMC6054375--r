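test_that("uniform fields are invariant under any balanced exchange", {
  g <- example_geometry("mini8")
  f <- generate_physics(g, seed = 2)
  st <- new_tracer_state(g, fill = 7.5)
  flux <- f$exchange[100, , ]
  st2 <- advect(st, g, flux)
  expect_equal(st2$conc[!is.na(st$conc)], st$conc[!is.na(st$conc)],
               tolerance = 1e-12)
})

test_that("two-box advective mixing matches the closed-form relaxation", {
  g <- two_box_geometry(two_faces = TRUE)
  V <- 1e7; Q <- 1e5
  dt <- V / (20 * Q)
  st <- new_tracer_state(g)
  st$conc[1, 1, "NO3"] <- 10; st$conc[2, 1, "NO3"] <- 0
  plan <- baltisim:::make_transport_plan(g)
  M <- baltisim:::conc_to_matrix(st); M[is.na(M)] <- 0
  maxrel <- 0
  for (i in 1:100) {
    # symmetric exchange Q in both directions, two half-steps per dt
    M <- baltisim:::advect_core(M, plan, c(Q * dt / 2, Q * dt / 2))
    M <- baltisim:::advect_core(M, plan, c(Q * dt / 2, Q * dt / 2))
    analytic <- 5 + 5 * exp(-2 * Q * (i * dt) / V)
    maxrel <- max(maxrel, abs(M[1, "NO3"] - analytic) / analytic)
  }
  expect_lt(maxrel, 0.01)
})

test_that("a dynamic box forced by a boundary box relaxes to its value", {
  g <- two_box_geometry(kind = c("boundary", "dynamic"), two_faces = TRUE)
  plan <- baltisim:::make_transport_plan(g)
  st <- new_tracer_state(g)
  st$conc[1, 1, "NO3"] <- 7; st$conc[2, 1, "NO3"] <- 0
  M <- baltisim:::conc_to_matrix(st); M[is.na(M)] <- 0
  for (i in 1:2000) {
    M <- baltisim:::advect_core(M, plan, c(1e5, 1e5))
    M[1, ] <- 7   # boundary held at c_ext
  }
  expect_equal(unname(M[2, "NO3"]), 7, tolerance = 1e-6)
})

test_that("advection rejects CFL violations and NaN forcing", {
  g <- two_box_geometry()
  st <- new_tracer_state(g, fill = 1)
  expect_error(advect(st, g, matrix(2e7, 1, 1)),
               class = "baltisim_cfl_error")
  expect_error(advect(st, g, matrix(NaN, 1, 1)),
               class = "baltisim_validation_error")
})

test_that("vertical mixing matches a brute-force tridiagonal integration", {
  g <- column_geometry(c(5, 10, 15))
  st <- new_tracer_state(g)
  st$conc[1, , "NO3"] <- c(9, 1, 4)
  plan <- baltisim:::make_transport_plan(g)
  M <- baltisim:::conc_to_matrix(st); M[is.na(M)] <- 0
  rate <- 2; dt <- 1e-3; nstep <- 1000
  for (i in seq_len(nstep)) M <- baltisim:::vertical_mix_core(M, plan, rate, dt)
  # independent dense Euler on the same tridiagonal system
  V <- g$volume[1, ]
  k <- rate * plan$mix$coef
  y <- c(9, 1, 4)
  for (i in seq_len(nstep)) {
    f1 <- k[1] * (y[1] - y[2]); f2 <- k[2] * (y[2] - y[3])
    y <- y + dt * c(-f1 / V[1], (f1 - f2) / V[2], f2 / V[3])
  }
  expect_lt(max(abs(M[1:3, "NO3"] - y)), 1e-8)
  # and stays close to an adaptive ODE solution of the continuous system
  skip_if_not_installed("deSolve")
  o <- deSolve::ode(c(9, 1, 4), c(0, nstep * dt), function(t, y, p) {
    f1 <- k[1] * (y[1] - y[2]); f2 <- k[2] * (y[2] - y[3])
    list(c(-f1 / V[1], (f1 - f2) / V[2], f2 / V[3]))
  }, NULL, atol = 1e-12, rtol = 1e-12)
  expect_lt(max(abs(M[1:3, "NO3"] - o[2, 2:4])), 1e-4)
})

test_that("mixing conserves column mass and never increases variance", {
  g <- column_geometry(c(5, 10, 30, 40))
  st <- new_tracer_state(g)
  st$conc[1, , "NH4"] <- c(10, 0, 5, 1)
  plan <- baltisim:::make_transport_plan(g)
  M <- baltisim:::conc_to_matrix(st); M[is.na(M)] <- 0
  V <- g$volume[1, ]
  m0 <- sum(M[1:4, "NH4"] * V)
  v_prev <- stats::var(M[1:4, "NH4"])
  for (i in 1:50) {
    M <- baltisim:::vertical_mix_core(M, plan, 5, 0.5)
    expect_equal(sum(M[1:4, "NH4"] * V), m0, tolerance = 1e-12)
    v_now <- stats::var(M[1:4, "NH4"])
    expect_lte(v_now, v_prev + 1e-12)
    v_prev <- v_now
  }
  # zero rate leaves the state untouched
  M2 <- baltisim:::vertical_mix_core(M, plan, 0, 0.5)
  expect_identical(M2, M)
})

test_that("settling is an absorbing flux into the sediment", {
  g <- column_geometry(c(5, 10, 15))
  st <- new_tracer_state(g)
  st$conc[1, , "DL"] <- c(50, 0, 0)
  plan <- baltisim:::make_transport_plan(g)
  M <- baltisim:::conc_to_matrix(st); M[is.na(M)] <- 0
  sed <- st$sed
  V <- g$volume[1, ]
  m0 <- sum(M[1:3, "DL"] * V)
  tp <- transport_params()
  for (i in 1:1000) {
    out <- baltisim:::settle_core(M, sed, plan, tp$settling_velocity, 0.5)
    M <- out$M; sed <- out$sed
    expect_equal(sum(M[1:3, "DL"] * V) + unname(sed[1, "DLs"]), m0,
                 tolerance = 1e-9)
  }
  expect_equal(unname(sed[1, "DLs"]), m0, tolerance = 1e-9 * m0)
  expect_lt(sum(M[1:3, "DL"] * V) / m0, 1e-9)
  # zero velocity leaves the state unchanged
  out <- baltisim:::settle_core(M, sed, plan, c(DL = 0), 0.5)
  expect_identical(out$M, M)
  # settling a dissolved tracer is a configuration error
  expect_error(transport_params(settling_velocity = c(NO3 = 1)),
               class = "baltisim_validation_error")
})
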