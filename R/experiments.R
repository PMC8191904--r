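# Scripted in-silico experiments: forcing fixtures, residual-fraction
# sweeps, temperature regimes, acidification, one-at-a-time sensitivity.

#' Generate a forcing-series fixture
#'
#' @param kind One of `"constant"`, `"sinusoid"`, `"step"`, `"composite"`
#'   (sinusoid plus step offset) or `"noisy-seasonal"` (sinusoid plus
#'   seeded Gaussian noise).
#' @param duration Length, d.
#' @param dt Resolution, d (default daily).
#' @param temp_c Constant temperature (constant kind), degC.
#' @param mean,amplitude,period,phase Sinusoid parameters (degC, d); the
#'   minimum falls at `t = phase`, the peak half a period later.
#' @param base,step_to,t_on,step_duration Step parameters: temperature is
#'   `base` except in `[t_on, t_on + step_duration)` where it is `step_to`.
#' @param noise_sd Noise standard deviation (degC).
#' @param ph pH, scalar or one value per time point.
#' @param seed Seed for the noisy kind; deterministic output given the seed.
#' @return A [forcing_series()].
#' @export
make_forcings <- function(kind = c("constant", "sinusoid", "step",
                                   "composite", "noisy-seasonal"),
                          duration = 365, dt = 1, temp_c = 20,
                          mean = 12, amplitude = 10, period = 365, phase = 0,
                          base = 20, step_to = 10, t_on = 100,
                          step_duration = 10,
                          noise_sd = 1, ph = 7, seed = 1) {
  kind <- match.arg(kind)
  times <- seq(0, duration, by = dt)
  sinus <- function(t) mean - amplitude * cos(2 * pi * (t - phase) / period)
  stepf <- function(t) ifelse(t >= t_on & t < t_on + step_duration,
                              step_to, base)
  temp <- switch(kind,
    "constant" = rep(temp_c, length(times)),
    "sinusoid" = sinus(times),
    "step" = stepf(times),
    "composite" = sinus(times) + (stepf(times) - base),
    "noisy-seasonal" = {
      set.seed(seed)
      sinus(times) + stats::rnorm(length(times), 0, noise_sd)
    })
  forcing_series(times, temp_c = temp, ph = ph)
}

#' Residual-fraction and enrichment sweep
#'
#' Crosses residual fractions with enrichment factors and reports cumulative
#' CH4 and methanogen biomass for each combination. Washout of active
#' methanogens at small residual fractions is the mechanism by which
#' frequent emptying cuts emission.
#'
#' @param template Scenario template; management is overridden per cell.
#' @param f_resid_values Residual fractions, each in (0, 1).
#' @param a_enrich_values Enrichment factors.
#' @return Tidy long data frame: `f_resid`, `a_enrich`, `metric`
#'   (`cum_CH4_g`, `mean_methanogen_biomass_g`, `final_methanogen_biomass_g`,
#'   `mean_X_<id>`), `value`.
#' @export
residual_fraction_sweep <- function(template,
                                    f_resid_values = c(0.005, 0.1, 0.5),
                                    a_enrich_values = c(0, 5)) {
  if (any(f_resid_values <= 0 | f_resid_values >= 1))
    stop("f_resid values must be in (0, 1)")
  grid <- expand.grid(f_resid = f_resid_values, a_enrich = a_enrich_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    scn <- template
    scn$management <- management_scheme(
      F_in = template$management$F_in, M_max = template$management$M_max,
      f_resid = grid$f_resid[i], a_enrich = grid$a_enrich[i],
      mode = template$management$mode, times = template$management$times)
    traj <- simulate_slurry(scn)
    st <- traj$states
    xc <- traj$group_state_cols
    meth <- xc[!vapply(scn$groups, `[[`, FALSE, "is_sulfate_reducer")]
    tot <- rowSums(st[, meth, drop = FALSE])
    w <- diff(st$time); mid <- function(v) (v[-1] + v[-length(v)]) / 2
    tmean <- function(v) sum(mid(v) * w) / sum(w)
    vals <- c(cum_CH4_g = traj$summary$CH4_cum_g,
              mean_methanogen_biomass_g = tmean(tot),
              final_methanogen_biomass_g = tot[length(tot)],
              vapply(xc, function(cn) tmean(st[[cn]]), 0) |>
                stats::setNames(paste0("mean_", xc)))
    data.frame(f_resid = grid$f_resid[i], a_enrich = grid$a_enrich[i],
               metric = names(vals), value = unname(vals))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Spin a template up at constant temperature so regime experiments start
# from an adapted community rather than the influent inoculum.
warmed_state <- function(template, temp_c = 20, ph = 7, f_resid = 0.95,
                         cycle_length = 180, max_cycles = 4) {
  scn <- template
  scn$forcings <- forcing_series(0, temp_c = temp_c, ph = ph)
  scn$management <- management_scheme(
    F_in = template$management$F_in, M_max = template$management$M_max,
    f_resid = f_resid, a_enrich = template$management$a_enrich)
  traj <- run_to_periodic_steady_state(scn, cycle_length, max_cycles,
                                       tol = 1e-2)
  traj$summary$final_state
}

daily_metrics <- function(traj) {
  st <- traj$states
  meth <- traj$group_state_cols[
    !vapply(traj$scenario$groups, `[[`, FALSE, "is_sulfate_reducer")]
  data.frame(time = st$time, temp_c = st$temp_c, ph = st$ph,
             CH4_rate = st$rate_CH4,
             CH4_cum = st$CH4_cum,
             VFA = st$VFA,
             methanogen_biomass = rowSums(st[, meth, drop = FALSE]))
}

#' Temperature-regime experiment
#'
#' Either a seasonal sinusoid (run to a periodic orbit, exposing the
#' hysteresis between the temperature peak and the CH4 peak) or a cold step
#' (instantaneous temperature drop of a given duration followed by
#' rewarming, exposing the spike-after-rewarming vs prolonged-suppression
#' contrast between short and long cold periods).
#'
#' @param template Scenario template.
#' @param regime `"seasonal-sinusoid"` or `"step-drop"`.
#' @param f_resid Residual fraction for the regime run.
#' @param mean,amplitude,period Sinusoid parameters (degC, d).
#' @param warmup_cycles Seasonal warm-up cycles before the reported cycle.
#' @param T_base,T_cold Warm and cold temperatures (degC) for the step.
#' @param t_drop Time of the drop (d) after the start.
#' @param drop_duration Cold-period length, d (10 for a transient, 300+ for
#'   community turnover).
#' @param recovery Days simulated after rewarming.
#' @return List with `trajectory` (final-cycle `slurry_trajectory`) and
#'   `metrics` (daily temperature, CH4 emission rate, cumulative CH4, VFA,
#'   methanogen biomass).
#' @export
temperature_regime_experiment <- function(template,
                                          regime = c("seasonal-sinusoid",
                                                     "step-drop"),
                                          f_resid = 0.95,
                                          mean = 12, amplitude = 10,
                                          period = 365, warmup_cycles = 4,
                                          T_base = 20, T_cold = 5,
                                          t_drop = 100, drop_duration = 10,
                                          recovery = 200) {
  regime <- match.arg(regime)
  scn <- template
  scn$management <- management_scheme(
    F_in = template$management$F_in, M_max = template$management$M_max,
    f_resid = f_resid, a_enrich = template$management$a_enrich)
  if (regime == "seasonal-sinusoid") {
    scn$forcings <- make_forcings("sinusoid", duration = period,
                                  mean = mean, amplitude = amplitude,
                                  period = period)
    scn$duration <- period
    traj <- run_to_periodic_steady_state(scn, period,
                                         max_cycles = warmup_cycles,
                                         tol = 1e-3)
  } else {
    scn$forcings <- make_forcings("step",
                                  duration = t_drop + drop_duration + recovery,
                                  base = T_base, step_to = T_cold,
                                  t_on = t_drop,
                                  step_duration = drop_duration)
    scn$duration <- t_drop + drop_duration + recovery
    init <- warmed_state(template, temp_c = T_base, f_resid = f_resid)
    traj <- simulate_slurry(scn, initial = init)
  }
  list(trajectory = traj, metrics = daily_metrics(traj))
}

#' Acidification experiment
#'
#' Step the slurry pH down (as in sulfuric-acid treatment) and back up.
#' Acid dosing is represented by an elevated influent sulfate concentration
#' during the acidified window only; outside it the influent reverts to the
#' template value. With the sulfate-reducer group included, the sulfate
#' accumulated during treatment keeps sr1 competing for VFA (and producing
#' inhibitory sulfide) after the pH is restored, which makes the CH4
#' rebound smaller and later.
#'
#' The run is stitched from three phases (pre-acid, acidified, restored),
#' carrying the full reactor state across the phase boundaries.
#'
#' @param template Scenario template (its groups are replaced by the
#'   default community, with or without sr1).
#' @param pH_low Acidified pH.
#' @param t_down,t_up Times (d) of the pH drop and restoration.
#' @param include_sulfate_reducer Include sr1?
#' @param SO4_influent_acid Influent sulfate (g SO4-S per kg) while
#'   acidified (sulfuric-acid dosing).
#' @param f_resid Residual fraction.
#' @param duration Total simulated days.
#' @param temp_c Constant temperature, degC.
#' @return List with `phases` (one `slurry_trajectory` per phase) and
#'   stitched daily `metrics` on the global clock.
#' @export
acidification_experiment <- function(template, pH_low = 5.5,
                                     t_down = 60, t_up = 180,
                                     include_sulfate_reducer = FALSE,
                                     SO4_influent_acid = 1.5,
                                     f_resid = 0.95, duration = 500,
                                     temp_c = 20) {
  scn <- template
  scn$groups <- default_groups(include_sulfate_reducer)
  scn$management <- management_scheme(
    F_in = template$management$F_in, M_max = template$management$M_max,
    f_resid = f_resid, a_enrich = template$management$a_enrich)
  phase <- function(init, len, ph, C_SO4_in) {
    s <- scn
    s$duration <- len
    s$forcings <- forcing_series(0, temp_c = temp_c, ph = ph)
    s$influent$C_SO4_in <- C_SO4_in
    simulate_slurry(s, initial = init)
  }
  init <- warmed_state(scn, temp_c = temp_c, f_resid = f_resid)
  base_SO4 <- template$influent$C_SO4_in
  A <- phase(init, t_down, 7, base_SO4)
  B <- phase(A$summary$final_state, t_up - t_down, pH_low, SO4_influent_acid)
  C <- phase(B$summary$final_state, duration - t_up, 7, base_SO4)
  shift <- function(tr, off) { m <- daily_metrics(tr); m$time <- m$time + off; m }
  metrics <- rbind(shift(A, 0), shift(B, t_down), shift(C, t_up))
  list(phases = list(pre = A, acid = B, restored = C), metrics = metrics)
}

# Default one-at-a-time sensitivity set: model parameters and inputs, each
# a function applying a multiplicative factor to a scenario.
sensitivity_parameter_set <- function() {
  set_groups <- function(scn, field, fac) {
    scn$groups <- lapply(scn$groups, function(g) {
      g[[field]] <- g[[field]] * fac
      if (field == "Y" && g$Y >= 1) g$Y <- 0.999
      g
    })
    scn
  }
  list(
    alpha_opt = list(type = "parameter", apply = function(scn, fac) {
      scn$hydrolysis$rate_opt <- scn$hydrolysis$rate_opt * fac; scn
    }),
    Y = list(type = "parameter", apply = function(scn, fac)
      set_groups(scn, "Y", fac)),
    qmax_opt = list(type = "parameter", apply = function(scn, fac) {
      scn$groups <- lapply(scn$groups, function(g) {
        g$cardinal$rate_opt <- g$cardinal$rate_opt * fac; g
      }); scn
    }),
    KS_k1 = list(type = "parameter", apply = function(scn, fac) {
      scn$ks_params$k1 <- scn$ks_params$k1 * fac; scn
    }),
    k_d = list(type = "parameter", apply = function(scn, fac)
      set_groups(scn, "k_d", fac)),
    temperature = list(type = "input", apply = function(scn, fac) {
      scn$forcings$temp_c <- scn$forcings$temp_c * fac; scn
    }),
    C_Sp_in = list(type = "input", apply = function(scn, fac) {
      scn$influent$C_Sp_in <- scn$influent$C_Sp_in * fac; scn
    }),
    influent_biomass = list(type = "input", apply = function(scn, fac) {
      scn$groups <- lapply(scn$groups, function(g) {
        g$C_X_in <- g$C_X_in * fac; g
      }); scn
    })
  )
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each parameter or input by the given fractional amounts and
#' reports the fractional change in cumulative CH4 relative to the
#' unperturbed template, sorted by the largest absolute response.
#'
#' @param template Scenario to perturb.
#' @param parameters Character vector naming entries of the default set
#'   (`alpha_opt`, `Y`, `qmax_opt`, `KS_k1`, `k_d`, `temperature`,
#'   `C_Sp_in`, `influent_biomass`); default all.
#' @param perturbation_fractions Nonzero fractional perturbations
#'   (default +/-50%).
#' @return Data frame: `parameter`, `type` (`parameter`/`input`),
#'   `perturbation`, `response` (fractional change in cumulative CH4),
#'   ordered by decreasing max |response| per parameter.
#' @export
sensitivity_analysis <- function(template, parameters = NULL,
                                 perturbation_fractions = c(-0.5, 0.5)) {
  if (any(perturbation_fractions == 0))
    stop("perturbations must be nonzero")
  pset <- sensitivity_parameter_set()
  if (is.null(parameters)) parameters <- names(pset)
  if (!all(parameters %in% names(pset)))
    stop("unknown parameter(s): ",
         paste(setdiff(parameters, names(pset)), collapse = ", "))
  base <- simulate_slurry(template)$summary$CH4_cum_g
  rows <- list()
  for (pn in parameters) {
    for (fr in perturbation_fractions) {
      scn <- pset[[pn]]$apply(template, 1 + fr)
      ch4 <- simulate_slurry(scn)$summary$CH4_cum_g
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pn, type = pset[[pn]]$type, perturbation = fr,
        response = (ch4 - base) / base)
    }
  }
  out <- do.call(rbind, rows)
  rank <- tapply(abs(out$response), out$parameter, max)
  out <- out[order(-rank[out$parameter], out$parameter, out$perturbation), ]
  rownames(out) <- NULL
  out
}
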