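test_that("surface respiration is O2-transfer-limited and linear in area", {
  tp <- transfer_params(area = 10, kL_O2 = 100, kH_O2 = 24.2)
  expect_equal(surface_respiration(tp), 100 * 10 * 0.208 / 24.2)
  expect_equal(surface_respiration(transfer_params(kL_O2 = 0)), 0)
  tp2 <- transfer_params(area = 20, kL_O2 = 100, kH_O2 = 24.2)
  expect_equal(surface_respiration(tp2), 2 * surface_respiration(tp))
})

test_that("H2S emission is linear in concentration and area", {
  tp <- transfer_params(area = 10, kL_H2S = 10)
  expect_equal(h2s_emission_rate(tp, 0), 0)
  expect_equal(h2s_emission_rate(tp, 0.3), 10 * 10 * 0.3)
  expect_equal(h2s_emission_rate(transfer_params(area = 20, kL_H2S = 10), 0.3),
               2 * h2s_emission_rate(tp, 0.3))
  expect_error(h2s_emission_rate(tp, -1), ">= 0")
})

test_that("with no biomass, inflow or respiration, hydrolysis only shuffles Sp into VFA", {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7),
                       C_X_in = 0, X_init = 0)
  scn <- scenario(groups = list(g), duration = 5,
                  management = management_scheme(F_in = 0),
                  transfer = transfer_params(kL_O2 = 0, kL_H2S = 0))
  st <- initial_state(scn)
  d <- slurry_derivatives(1, st, scn)[[1]]
  expect_equal(d[["Sp"]] + d[["VFA"]], 0)
  expect_lt(d[["Sp"]], 0)
  expect_equal(d[["M"]], 0)
  expect_equal(d[["CH4_cum"]], 0)
})

test_that("the RHS matches an explicitly assembled Petersen matrix on random states", {
  set.seed(7)
  rng <- function(n, lo, hi) runif(n, lo, hi)
  for (with_sr in c(FALSE, TRUE)) {
    scn <- default_scenario(include_sulfate_reducer = with_sr)
    scn$influent$C_SO4_in <- 1.0
    for (k in 1:20) {
      st <- random_state(scn, rng)
      d <- slurry_derivatives(3.7, st, scn)[[1]]
      expect_equal(d, petersen_oracle(3.7, st, scn), tolerance = 1e-10)
    }
  }
})

test_that("the RHS conserves COD, sulfur and nitrogen on random states", {
  set.seed(11)
  rng <- function(n, lo, hi) runif(n, lo, hi)
  scn <- default_scenario(include_sulfate_reducer = TRUE)
  scn$influent$C_SO4_in <- 1.5
  scn$influent$C_H2S_in <- 0.05
  for (k in 1:25) {
    st <- random_state(scn, rng)
    d <- slurry_derivatives(runif(1, 0, 300), st, scn)[[1]]
    xs <- grep("^X_", names(d))
    cod_rate <- d[["Sp"]] + d[["VFA"]] + sum(d[xs]) + 4 * d[["CH4_cum"]] +
      2 * d[["sulfide"]] + 2 * d[["H2S_emitted_cum"]] + d[["COD_resp_cum"]]
    expect_equal(cod_rate, d[["COD_in_cum"]], tolerance = 1e-12)
    s_rate <- d[["SO4"]] + d[["sulfide"]] + d[["H2S_emitted_cum"]]
    expect_equal(s_rate, d[["S_in_cum"]], tolerance = 1e-12)
    expect_equal(d[["TAN"]], d[["TAN_in_cum"]])
  }
})

test_that("a state with all process rates switched off is a fixed point", {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7), k_d = 0,
                       C_X_in = 0)
  scn <- scenario(groups = list(g), duration = 5,
                  management = management_scheme(F_in = 0),
                  transfer = transfer_params(kL_O2 = 0, kL_H2S = 0),
                  forcings = forcing_series(0, temp_c = -10))  # below T_min
  st <- initial_state(scn)
  st[["sulfide"]] <- 0
  d <- slurry_derivatives(0, st, scn)[[1]]
  expect_equal(unname(d), rep(0, length(d)))
})

test_that("instantaneous CH4 production equals per-group productivity times uptake", {
  scn <- default_scenario()
  st <- initial_state(scn)
  st[grep("^X_", names(st))] <- 50
  st[["VFA"]] <- 2000
  out <- slurry_derivatives(2, st, scn)
  ex <- out[[2]]
  ids <- vapply(scn$groups, `[[`, "", "id")
  up <- ex[paste0("uptake_", ids)]
  expect_equal(out[[1]][["CH4_cum"]],
               sum((1 - 0.05) / 4 * up), tolerance = 1e-12)
})

test_that("cumulative emission pools never decrease along a trajectory", {
  tr <- simulate_slurry(default_scenario(duration = 70))
  expect_true(all(diff(tr$states$CH4_cum) >= 0))
  expect_true(all(diff(tr$states$CO2_cum) >= 0))
  expect_true(all(diff(tr$states$H2S_emitted_cum) >= 0))
  expect_true(all(diff(tr$states$time) >= 0))
})
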