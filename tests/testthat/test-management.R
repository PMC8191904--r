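test_that("retention fraction is the log-odds shift of the bulk residual", {
  expect_equal(retention_fraction(0.1, 0), 0.1)
  expect_equal(retention_fraction(0.5, 5), exp(5) / (1 + exp(5)),
               tolerance = 1e-12)
  expect_equal(retention_fraction(0.5, 5), 0.99331, tolerance = 1e-5)
  # identity at zero enrichment over a dense grid
  f <- seq(0.001, 0.999, by = 0.001)
  expect_equal(retention_fraction(f, 0), f, tolerance = 1e-12)
  # monotone increasing in a_enrich
  a <- seq(-4, 8, by = 0.5)
  expect_true(all(diff(retention_fraction(0.2, a)) > 0))
  expect_error(retention_fraction(0, 1), "logit")
  expect_error(retention_fraction(1, 1), "logit")
})

test_that("removal scales bulk pools by f_resid, biomass by the enriched fraction", {
  scn <- default_scenario()
  st <- initial_state(scn)
  st[["M"]] <- 33333
  st[grep("^X_", names(st))] <- c(5, 10, 20, 40, 80)
  sch <- management_scheme(f_resid = 0.1, a_enrich = 0)
  rem <- apply_removal(st, sch)
  expect_equal(rem$state[["M"]], 3333.3)
  # mass conservation per pool
  for (p in c("M", "Sp", "VFA", "SO4", "sulfide", "TAN"))
    expect_equal(rem$state[[p]] + rem$removed[[p]], st[[p]])
  xs <- grep("^X_", names(st), value = TRUE)
  for (p in xs)
    expect_equal(rem$state[[p]] + rem$removed[[paste0(p)]], st[[p]])
  # no enrichment: biomass scaled like the solutes
  expect_equal(unname(rem$state[xs]), unname(st[xs]) * 0.1)
  # solute concentrations unchanged across the event
  expect_equal(rem$state[["VFA"]] / rem$state[["M"]],
               st[["VFA"]] / st[["M"]])
  # counters untouched
  expect_equal(rem$state[["CH4_cum"]], st[["CH4_cum"]])

  rem5 <- apply_removal(st, management_scheme(f_resid = 0.1, a_enrich = 5))
  fX <- retention_fraction(0.1, 5)
  expect_equal(unname(rem5$state[xs]), unname(st[xs]) * fX)
  st0 <- st; st0[["M"]] <- 0
  expect_error(apply_removal(st0, sch), "empty")
})

test_that("threshold filling time follows (M_max - M) / F_in", {
  sch <- management_scheme(F_in = 1000, M_max = 33333, f_resid = 0.1)
  expect_equal(next_removal_time(3333.3, sch), 29.9997)
  expect_equal(next_removal_time(33333, sch), 0)
  sch2 <- management_scheme(F_in = 2000, M_max = 33333, f_resid = 0.1)
  expect_equal(next_removal_time(3333.3, sch2),
               next_removal_time(3333.3, sch) / 2)
  expect_equal(next_removal_time(100, management_scheme(F_in = 0)), Inf)
})

test_that("event cadence is periodic under constant filling", {
  tr <- simulate_slurry(default_scenario(duration = 200))
  iv <- diff(tr$events$time)
  expect_true(all(abs(iv - 33333 * 0.9 / 1000) < 1e-9))
  # first event from the residual initial mass has the same spacing
  expect_equal(tr$events$time[1], 33333 * 0.9 / 1000, tolerance = 1e-9)
})

test_that("scheme invariants are enforced", {
  expect_error(management_scheme(f_resid = 1.5), "f_resid")
  expect_error(management_scheme(M_max = -1), "M_max")
  expect_error(management_scheme(F_in = c(10, 20)), "constant F_in")
  expect_error(management_scheme(mode = "scheduled"), "times")
})
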