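# shared projection runs for the long-horizon tests; computed once per
# test session and reused across test blocks
.run_cache <- new.env(parent = emptyenv())

shared_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  g <- example_geometry("mini8")
  r <- if (name == "closed") {
    run_projection(g, years = 10, seed = 1, groups = zero_f_groups(),
                   closed = TRUE)
  } else {
    sc <- build_scenarios(g)
    run_projection(g, scenario = sc[[name]], seed = 1)
  }
  assign(name, r, envir = .run_cache)
  r
}

terminal_total <- function(run, group, window = 5) {
  sum(terminal_average(run, window)[group, ])
}

terminal_detritus <- function(run, window = 5) {
  yrs <- seq(run$years - window + 1, run$years)
  mean(rowSums(run$annual_detritus[yrs, , drop = FALSE]))
}
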