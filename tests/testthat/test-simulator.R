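test_that("forcing series validates monotone times and broadcasts scalars", {
  f <- forcing_series(c(0, 10, 20), temp_c = 15)
  expect_equal(f$temp_c, rep(15, 3))
  expect_error(forcing_series(c(0, 10, 10), 20), "strictly increasing")
  expect_error(forcing_series(c(0, 10), temp_c = c(1, 2, 3)), "match")
})

test_that("no methanogens means no methane, ever", {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7),
                       C_X_in = 0, X_init = 0)
  scn <- scenario(groups = list(g), duration = 40)
  tr <- simulate_slurry(scn)
  expect_equal(max(tr$states$CH4_cum), 0)
  # VFA then accumulates instead of being consumed
  expect_gt(tr$states$VFA[nrow(tr$states)], tr$states$VFA[1])
})

test_that("simulation is deterministic", {
  scn <- default_scenario(duration = 45)
  tr1 <- simulate_slurry(scn)
  tr2 <- simulate_slurry(scn)
  expect_identical(tr1$states, tr2$states)
  expect_identical(tr1$events, tr2$events)
})

test_that("state invariants hold on the output grid", {
  tr <- simulate_slurry(default_scenario(duration = 95))
  st <- tr$states
  for (p in c("M", "Sp", "VFA", "SO4", "TAN"))
    expect_true(all(st[[p]] >= -1e-6), label = p)
  expect_true(all(st$M <= 33333 * (1 + 1e-9)))
})

test_that("adaptive integration agrees with a fixed-step Euler oracle across one event", {
  scn <- default_scenario(duration = 5)
  # start two days short of capacity so one emptying falls mid-horizon
  init <- initial_state(scn)
  init[["M"]] <- 33333 - 2000
  for (p in c("Sp", "VFA", "SO4", "TAN"))
    init[[p]] <- init[[p]] / (0.1 * 33333) * init[["M"]]
  init[grep("^X_", names(init))] <-
    init[grep("^X_", names(init))] / (0.1 * 33333) * init[["M"]]
  tr <- simulate_slurry(scn, initial = init)
  expect_equal(tr$summary$n_events, 1)
  expect_equal(tr$events$time[1], 2)

  # same stepping scheme as euler_simulate(), from the shifted start
  oracle <- local({
    ctx <- slurrygas:::build_context(scn)
    forc <- slurrygas:::forcing_functions(scn)
    y <- init; t <- 0; h <- 1e-4
    repeat {
      t_event <- t + next_removal_time(y[["M"]], scn$management)
      t_end <- min(t_event, scn$duration)
      nstep <- round((t_end - t) / h)
      for (k in seq_len(nstep)) {
        y <- y + h * slurrygas:::reactor_rhs(t + (k - 1) * h, y, ctx, forc)[[1]]
      }
      t <- t_end
      if (t >= scn$duration - 1e-9) break
      y <- apply_removal(y, scn$management)$state
    }
    y
  })
  final <- tr$summary$final_state
  for (p in names(final)) {
    ref <- oracle[[p]]
    if (abs(ref) > 1e-6)
      expect_lt(abs(final[[p]] - ref) / abs(ref), 1e-3,
                label = paste("pool", p))
  }
})

test_that("warm-up cycling converges for constant forcings and honors tol = Inf", {
  scn <- default_scenario(duration = 60)
  one <- run_to_periodic_steady_state(scn, max_cycles = 5, tol = Inf)
  expect_equal(one$convergence$n_cycles, 1)
  expect_equal(one$summary$CH4_cum_g,
               simulate_slurry(scn)$summary$CH4_cum_g)
  multi <- run_to_periodic_steady_state(scn, max_cycles = 8, tol = 5e-3)
  expect_true(multi$convergence$converged)
  pc <- multi$convergence$per_cycle_CH4_g
  n <- length(pc)
  expect_lt(abs(pc[n] - pc[n - 1]) / pc[n - 1], 5e-3)
})

test_that("non-convergence yields a warning status, not an error", {
  scn <- default_scenario(duration = 30)
  expect_warning(run_to_periodic_steady_state(scn, max_cycles = 2, tol = 1e-12),
                 "not reached")
})

test_that("forced-mass management follows the observed series", {
  scn <- default_scenario(duration = 30)
  masses <- c(5000, 15000, 25000, 5000, 15000)
  scn$forcings <- forcing_series(c(0, 10, 20, 20.01, 30), temp_c = 20,
                                 slurry_mass = masses)
  scn$management <- management_scheme(F_in = 1000, M_max = 33333,
                                      f_resid = 0.1, mode = "forced-mass")
  tr <- simulate_slurry(scn)
  expect_equal(tr$summary$n_events, 1)
  expect_equal(tr$events$f_resid[1], 5000 / 25000)
  st <- tr$states
  expect_equal(st$M[st$time == 10][1], 15000, tolerance = 1e-6)
  expect_equal(st$M[nrow(st)], 15000, tolerance = 1e-6)
  expect_lt(cod_balance(tr), 1e-9)
})
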