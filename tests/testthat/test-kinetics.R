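test_that("CTM1 hits its anchors and the hand-evaluated point", {
  p <- cardinal_params(0, 50, 60, 0.02)
  expect_equal(cardinal_rate(50, p), 0.02)
  expect_equal(cardinal_rate(0, p), 0)
  expect_equal(cardinal_rate(60, p), 0)
  # hand evaluation: num = (20-60)(20-0)^2 = -16000,
  # den = 50*(50*(-30) - (-10)*10) = -70000 -> 0.02 * 16/70
  expect_equal(cardinal_rate(20, p), 0.02 * 16000 / 70000,
               tolerance = 1e-12)
  expect_equal(cardinal_rate(20, p), 0.0045714, tolerance = 1e-4)
})

test_that("CTM1 is clamped to zero outside the cardinal interval and peaks at T_opt", {
  p <- cardinal_params(5, 35, 45, 1.3)
  expect_equal(cardinal_rate(c(-10, 4, 46, 80), p), rep(0, 4))
  grid <- seq(5, 45, by = 0.01)
  r <- cardinal_rate(grid, p)
  expect_true(all(r >= 0))
  expect_equal(grid[which.max(r)], 35)
  expect_equal(max(r), 1.3, tolerance = 1e-6)
  # continuity across the clamp boundaries
  expect_lt(cardinal_rate(5 + 1e-6, p), 1e-4)
  expect_lt(cardinal_rate(45 - 1e-6, p), 1e-4)
  expect_error(cardinal_params(35, 5, 45, 1), "T_min < T_opt < T_max")
})

test_that("half-saturation constant decays exponentially with temperature", {
  p <- ks_temperature_params(1.4, 0.06)
  expect_equal(ks_at_temperature(0, 2, p), 2 * 1.4)
  T <- seq(-5, 55, by = 2.5)
  ks <- ks_at_temperature(T, 1, p)
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks > 0))
  # log K_S affine in T; 10-degree ratio independent of T
  expect_equal(diff(log(ks)) / diff(T), rep(-0.06, length(T) - 1))
  expect_equal(ks_at_temperature(T + 10, 1, p) / ks,
               rep(exp(-10 * 0.06), length(T)))
  expect_error(ks_temperature_params(-1, 0.05), "k1")
  expect_error(ks_temperature_params(1, 0), "k2")
})

test_that("linear q_max,opt rule anchors at 8 at 40 degC and passes through the origin", {
  expect_identical(qmax_opt_from_linear_rule(40), 8)
  expect_identical(qmax_opt_from_linear_rule(0), 0)
  expect_identical(qmax_opt_from_linear_rule(20), 4)
  expect_equal(qmax_opt_from_linear_rule(50), 10)  # extrapolated
  expect_error(qmax_opt_from_linear_rule(-5), ">= 0")
})

test_that("Monod uptake has the right limits and is linear in biomass", {
  expect_equal(methanogen_uptake_rate(0, 0.3, 5, 100), 0)
  expect_equal(methanogen_uptake_rate(0.3, 0.3, 5, 100), 5 * 100 / 2)
  expect_equal(methanogen_uptake_rate(1e9, 0.3, 5, 100), 5 * 100,
               tolerance = 1e-6)
  expect_equal(methanogen_uptake_rate(1.1, 0.3, 5, 0), 0)
  r1 <- methanogen_uptake_rate(1.1, 0.3, 5, 7, 0.5)
  expect_equal(methanogen_uptake_rate(1.1, 0.3, 5, 3 * 7, 0.5), 3 * r1)
  expect_error(methanogen_uptake_rate(1, 0.3, 5, 1, 1.2), "\\[0, 1\\]")
})

test_that("double-Monod sulfate reduction collapses to single Monod when sulfate saturates", {
  expect_equal(sulfate_reduction_rate(1, 0, 0.3, 0.02, 5, 10), 0)
  expect_equal(sulfate_reduction_rate(0.3, 0.02, 0.3, 0.02, 5, 10),
               5 * 10 / 4)
  expect_equal(sulfate_reduction_rate(1, 1e9, 0.3, 0.02, 5, 10),
               methanogen_uptake_rate(1, 0.3, 5, 10), tolerance = 1e-6)
})

test_that("inhibition product is 1 under benign conditions and 0 under extreme sulfide", {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7))
  pH_opt <- with(g$inhibition, (pH_LL + pH_UL) / 2)
  expect_equal(inhibition_product(pH_opt, 0, 0, 0, g), 1)
  expect_lt(inhibition_product(pH_opt, 0, 0, 1e9, g), 1e-6)
  # pH step down from neutral cuts the factor
  expect_lt(inhibition_product(5.5, 0, 0, 0, g),
            inhibition_product(7.0, 0, 0, 0, g))
})

test_that("inhibition product stays in [0,1] and is monotone in each inhibitor", {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7))
  set.seed(42)
  for (k in 1:200) {
    I <- inhibition_product(runif(1, 3, 11), runif(1, 0, 5),
                            runif(1, 0, 50), runif(1, 0, 5), g)
    expect_true(I >= 0 && I <= 1)
  }
  conc <- seq(0, 2, by = 0.05)
  for (pick in c("NH3", "NH4", "H2S")) {
    I <- vapply(conc, function(cc)
      inhibition_product(7, ifelse(pick == "NH3", cc, 0),
                         ifelse(pick == "NH4", cc, 0),
                         ifelse(pick == "H2S", cc, 0), g), 0)
    expect_true(all(diff(I) <= 0))
  }
})

test_that("ammonia speciation conserves TAN and splits evenly at pH = pKa", {
  sp <- speciation_params()
  s <- speciate_tan(10, 7.2, 25, sp)
  expect_equal(s$NH3 + s$NH4, 10)
  pka <- slurrygas:::pka_ammonia(25, sp)
  s2 <- speciate_tan(10, pka, 25, sp)
  expect_equal(s2$NH3, 5, tolerance = 1e-12)
  expect_lt(speciate_tan(10, 0.01, 25, sp)$NH3, 1e-8)
  expect_equal(speciate_tan(0, 7, 25, sp)$NH3, 0)
  # warmer slurry shifts the split toward free ammonia
  expect_gt(speciate_tan(10, 7, 35, sp)$NH3, speciate_tan(10, 7, 15, sp)$NH3)
})

test_that("sulfide speciation is half-unionized at pH = pKa1 and needs positive mass", {
  sp <- speciation_params()
  pka <- slurrygas:::pka_h2s(20, sp)
  expect_equal(speciate_sulfide(8, pka, 20, 2, sp), 8 * 0.5 / 2)
  expect_lt(speciate_sulfide(8, pka + 6, 20, 2, sp), 1e-5)
  expect_equal(speciate_sulfide(0, 7, 20, 2, sp), 0)
  expect_error(speciate_sulfide(1, 7, 20, 0, sp), "mass")
})
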