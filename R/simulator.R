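# Orchestration: forcings, scenario assembly, event-aware integration,
# warm-up cycling and steady-state extraction.

#' Time-varying forcings
#'
#' Temperature, pH and (optionally, for forced-mass management) slurry mass
#' as piecewise-linear time series; constant extrapolation outside the
#' range. Scalars are accepted for constant forcings.
#'
#' @param times Times (d), strictly increasing.
#' @param temp_c Temperature (degC): scalar or one value per time.
#' @param ph pH: scalar or one value per time.
#' @param slurry_mass Optional observed slurry mass (kg) per time.
#' @return An object of class `forcing_series`.
#' @export
forcing_series <- function(times = 0, temp_c = 20, ph = 7,
                           slurry_mass = NULL) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("forcing times must be strictly increasing")
  rec <- function(x) if (length(x) == 1) rep(x, length(times)) else x
  temp_c <- rec(temp_c); ph <- rec(ph)
  if (length(temp_c) != length(times) || length(ph) != length(times))
    stop("forcing columns must match the time vector length")
  if (!is.null(slurry_mass) && length(slurry_mass) != length(times))
    stop("slurry_mass must match the time vector length")
  structure(list(times = times, temp_c = temp_c, ph = ph,
                 slurry_mass = slurry_mass),
            class = "forcing_series")
}

# Interpolators (rule = 2: constant extrapolation).
forcing_functions <- function(scenario) {
  f <- scenario$forcings
  mk <- function(y) {
    if (length(f$times) == 1) {
      y0 <- y[1]
      function(t) y0
    } else stats::approxfun(f$times, y, rule = 2)
  }
  F_const <- if (scenario$management$mode == "threshold")
    scenario$management$F_in else 0
  list(temperature = mk(f$temp_c), ph = mk(f$ph),
       F_in = function(t) F_const)
}

#' Solver settings
#'
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable with automatic switching).
#' @param rtol,atol Relative/absolute tolerances.
#' @param hmax Maximum step (d); `NULL` lets the solver choose.
#' @param gate_eps Smooth-gating scale (g) that keeps surface respiration
#'   from driving the particulate pool negative.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(method = "lsoda", rtol = 1e-8, atol = 1e-6,
                            hmax = NULL, gate_eps = 0.01) {
  structure(list(method = method, rtol = rtol, atol = atol, hmax = hmax,
                 gate_eps = gate_eps),
            class = "solver_settings")
}

#' Assemble a complete simulation scenario
#'
#' @param groups List of [microbial_group()] objects (at least one).
#' @param hydrolysis [cardinal_params()] for the combined
#'   disintegration/hydrolysis/fermentation rate constant alpha
#'   (`rate_opt` = alpha_opt, per d).
#' @param ks_params [ks_temperature_params()] shared by all groups.
#' @param influent [influent_composition()].
#' @param management [management_scheme()].
#' @param transfer [transfer_params()].
#' @param productivities [co2_productivities()]; per-group methane
#'   productivity is derived from each group's yield unless `P_CH4` is
#'   overridden there.
#' @param forcings [forcing_series()].
#' @param speciation [speciation_params()].
#' @param solver [solver_settings()].
#' @param duration Simulated time (d), > 0.
#' @param n_warmup_cycles Default cycle count for
#'   [run_to_periodic_steady_state()].
#' @param output_dt Output grid spacing (d).
#' @return An object of class `scenario`.
#' @export
scenario <- function(groups = default_groups(),
                     hydrolysis = cardinal_params(0, 50, 60, 0.02),
                     ks_params = ks_temperature_params(1.0, 0.05),
                     influent = influent_composition(),
                     management = management_scheme(),
                     transfer = transfer_params(),
                     productivities = co2_productivities(),
                     forcings = forcing_series(),
                     speciation = speciation_params(),
                     solver = solver_settings(),
                     duration = 365, n_warmup_cycles = 5, output_dt = 1) {
  if (length(groups) < 1) stop("at least one microbial group is required")
  if (duration <= 0) stop("duration must be > 0")
  if (sum(vapply(groups, `[[`, FALSE, "is_sulfate_reducer")) > 1)
    stop("at most one sulfate reducer group")
  if (management$mode == "forced-mass" && is.null(forcings$slurry_mass))
    stop("forced-mass management needs a slurry_mass forcing series")
  structure(list(groups = groups, hydrolysis = hydrolysis,
                 ks_params = ks_params, influent = influent,
                 management = management, transfer = transfer,
                 productivities = productivities, forcings = forcings,
                 speciation = speciation, solver = solver,
                 duration = duration, n_warmup_cycles = n_warmup_cycles,
                 output_dt = output_dt),
            class = "scenario")
}

#' Initial reactor state for a scenario
#'
#' Default: slurry mass `f_resid * M_max` (the post-removal residual, which
#' makes the default threshold scenario periodic from the first cycle; the
#' first value of the mass series in forced-mass mode) with all pool
#' concentrations equal to the influent composition; per-group biomass from
#' `X_init` when set, else `M0 * C_X_in`. All cumulative counters start at
#' zero.
#'
#' @param scenario A [scenario()] object.
#' @return Named numeric state vector.
#' @export
initial_state <- function(scenario) {
  mgmt <- scenario$management
  M0 <- if (mgmt$mode == "forced-mass") {
    scenario$forcings$slurry_mass[1]
  } else mgmt$f_resid * mgmt$M_max
  inf <- scenario$influent
  X0 <- vapply(scenario$groups, function(g)
    if (is.null(g$X_init)) M0 * g$C_X_in else g$X_init, 0)
  ids <- vapply(scenario$groups, `[[`, "", "id")
  st <- c(M0, M0 * inf$C_Sp_in, M0 * inf$C_VFA_in, M0 * inf$C_SO4_in,
          M0 * inf$C_H2S_in, M0 * inf$C_TAN_in, X0,
          rep(0, 7))
  stats::setNames(st, state_template(ids))
}

# Integrate one continuous segment [t0, t1] and return the deSolve matrix.
integrate_segment <- function(state, t0, t1, ctx, forc, solver, dt) {
  if (t1 <= t0) return(NULL)
  grid <- seq(ceiling(t0 / dt) * dt, floor(t1 / dt) * dt, by = dt)
  times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
  args <- list(y = state, times = times,
               func = function(t, y, p) reactor_rhs(t, y, ctx, forc),
               parms = NULL, method = solver$method,
               rtol = solver$rtol, atol = solver$atol)
  if (!is.null(solver$hmax)) args$hmax <- solver$hmax
  out <- do.call(deSolve::ode, args)
  if (attr(out, "istate")[1] < 0)
    warning("solver reported trouble in segment [", t0, ", ", t1, "]")
  out
}

empty_event_log <- function(ids) {
  cols <- c("time", "M_pre", "removed_M", "removed_Sp", "removed_VFA",
            "removed_SO4", "removed_sulfide", "removed_TAN", "removed_X",
            paste0("removed_X_", ids), "f_resid", "f_resid_X")
  as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

event_row <- function(t, state_pre, rem) {
  data.frame(time = t, M_pre = unname(state_pre[["M"]]),
             removed_M = unname(rem$removed[["M"]]),
             removed_Sp = unname(rem$removed[["Sp"]]),
             removed_VFA = unname(rem$removed[["VFA"]]),
             removed_SO4 = unname(rem$removed[["SO4"]]),
             removed_sulfide = unname(rem$removed[["sulfide"]]),
             removed_TAN = unname(rem$removed[["TAN"]]),
             removed_X = unname(rem$removed[["X"]]),
             as.list(stats::setNames(
               unname(rem$removed[grep("^X_", names(rem$removed))]),
               paste0("removed_",
                      grep("^X_", names(rem$removed), value = TRUE)))),
             f_resid = rem$f_resid, f_resid_X = rem$f_resid_X,
             check.names = FALSE)
}

#' Simulate a scenario
#'
#' Integrates the reactor dynamics with a stiff-capable adaptive solver
#' between management events and applies instantaneous removals at each
#' event. Deterministic: identical scenarios give identical trajectories.
#'
#' @param scn A [scenario()] object.
#' @param initial Optional state vector overriding [initial_state()] (used
#'   to carry state across warm-up cycles).
#' @return An object of class `slurry_trajectory`: `states` (data frame of
#'   the state, per-process rates and inhibition factors on the output
#'   grid; event times appear twice, pre- and post-removal), `events`
#'   (removal log), `scenario`, `summary` (cumulative emissions, event
#'   count, final state).
#' @export
simulate_slurry <- function(scn, initial = NULL) {
  stopifnot(inherits(scn, "scenario"))
  ctx <- build_context(scn)
  forc <- forcing_functions(scn)
  mgmt <- scn$management
  state <- if (is.null(initial)) initial_state(scn) else initial
  if (length(state) != length(ctx$state_names))
    stop("initial state has wrong length")
  names(state) <- ctx$state_names
  dt <- scn$output_dt
  dur <- scn$duration
  ids <- ctx$ids
  events <- empty_event_log(ids)
  rows <- list()
  t <- 0

  push_segment <- function(out) {
    if (is.null(out)) return()
    df <- as.data.frame(out)
    rows[[length(rows) + 1]] <<- df
  }

  if (mgmt$mode == "forced-mass") {
    f <- scn$forcings
    kt <- f$times; km <- f$slurry_mass
    state[["M"]] <- km[1]
    for (j in seq_len(length(kt) - 1)) {
      if (kt[j] >= dur) break
      t0 <- kt[j]; t1 <- min(kt[j + 1], dur)
      dM <- km[j + 1] - km[j]
      if (dM < 0) {
        fov <- km[j + 1] / km[j]
        rem <- apply_removal(state, mgmt, f_override = fov)
        events <- rbind(events, event_row(t0, state, rem))
        state <- rem$state
        seg_forc <- forc; seg_forc$F_in <- function(t) 0
      } else {
        rate <- dM / (kt[j + 1] - kt[j])
        seg_forc <- forc; seg_forc$F_in <- function(t) rate
      }
      out <- integrate_segment(state, t0, t1, ctx, seg_forc, scn$solver, dt)
      push_segment(out)
      state <- out[nrow(out), ctx$state_names]
      t <- t1
    }
  } else {
    # threshold or scheduled: constant F_in
    repeat {
      t_event <- if (mgmt$mode == "threshold") {
        t + next_removal_time(state[["M"]], mgmt)
      } else {
        nxt <- mgmt$times[mgmt$times > t + 1e-12]
        if (length(nxt)) min(nxt) else Inf
      }
      t1 <- min(t_event, dur)
      if (t1 > t) {
        out <- integrate_segment(state, t, t1, ctx, forc, scn$solver, dt)
        push_segment(out)
        state <- out[nrow(out), ctx$state_names]
      }
      t <- t1
      if (t >= dur) break
      rem <- apply_removal(state, mgmt)
      events <- rbind(events, event_row(t, state, rem))
      state <- rem$state
    }
  }

  states <- do.call(rbind, rows)
  # drop duplicated interior segment-start rows that repeat the previous
  # segment's final (identical) record, keep pre/post event duplicates
  states <- states[!duplicated(states), , drop = FALSE]
  rownames(states) <- NULL
  per_cycle <- if (nrow(events)) {
    bounds <- c(0, events$time, dur)
    ch4_at <- stats::approx(states$time, states$CH4_cum, xout = bounds,
                            ties = "ordered")$y
    diff(ch4_at)
  } else states$CH4_cum[nrow(states)] - states$CH4_cum[1]
  final <- unlist(states[nrow(states), ctx$state_names])
  summary <- list(
    CH4_cum_g = unname(final[["CH4_cum"]]),
    CO2_cum_g = unname(final[["CO2_cum"]]),
    H2S_emitted_cum_g = unname(final[["H2S_emitted_cum"]]),
    n_events = nrow(events),
    duration_d = dur,
    per_cycle_CH4_g = per_cycle,
    final_state = final
  )
  structure(list(states = states, events = events, scenario = scn,
                 summary = summary,
                 group_state_cols = paste0("X_", ids),
                 convergence = NULL),
            class = "slurry_trajectory")
}

#' @export
print.slurry_trajectory <- function(x, ...) {
  s <- x$summary
  cat("<slurry_trajectory> ", s$duration_d, " d, ", s$n_events,
      " removal events\n", sep = "")
  cat(sprintf("  CH4 %.4g g   CO2 %.4g g   H2S %.4g g S\n",
              s$CH4_cum_g, s$CO2_cum_g, s$H2S_emitted_cum_g))
  invisible(x)
}

#' Repeat a forcing cycle to a periodic steady state
#'
#' Simulates consecutive cycles of length `cycle_length`, carrying the
#' state across cycles, until the per-cycle cumulative CH4 changes by less
#' than `tol` (relative) or `max_cycles` is reached. With `tol = Inf`
#' exactly one cycle is run, identical to [simulate_slurry()].
#'
#' @param scn A [scenario()] whose forcings are periodic with period
#'   `cycle_length`.
#' @param cycle_length Cycle length, d (default: the scenario duration).
#' @param max_cycles Maximum number of cycles (default: the scenario's
#'   `n_warmup_cycles`).
#' @param tol Relative per-cycle CH4 change below which the orbit is
#'   declared periodic.
#' @return The final-cycle `slurry_trajectory` with a `convergence` field:
#'   `converged`, `n_cycles`, `per_cycle_CH4_g`. Non-convergence gives a
#'   warning status, not an error.
#' @export
run_to_periodic_steady_state <- function(scn, cycle_length = scn$duration,
                                         max_cycles = scn$n_warmup_cycles,
                                         tol = 1e-3) {
  scn$duration <- cycle_length
  state <- initial_state(scn)
  per_cycle <- numeric(0)
  traj <- NULL
  converged <- FALSE
  for (k in seq_len(max_cycles)) {
    traj <- simulate_slurry(scn, initial = state)
    state <- traj$summary$final_state
    ch4 <- sum(traj$summary$per_cycle_CH4_g)
    per_cycle <- c(per_cycle, ch4)
    if (k > 1) {
      prev <- per_cycle[k - 1]
      if (is.finite(tol) && prev > 0 &&
          abs(ch4 - prev) / prev < tol) { converged <- TRUE; break }
      if (!is.finite(tol)) break
    }
    if (!is.finite(tol) && k == 1) break
  }
  if (!converged && is.finite(tol) && length(per_cycle) >= max_cycles)
    warning("periodic steady state not reached within ", max_cycles,
            " cycles")
  traj$convergence <- list(converged = converged,
                           n_cycles = length(per_cycle),
                           per_cycle_CH4_g = per_cycle)
  traj
}

#' Steady-state biomass at a fixed temperature
#'
#' Long-run per-cycle-averaged biomass of every group at constant
#' temperature, by default with a large residual fraction (0.95) so the
#' community composition, not washout, controls the outcome.
#'
#' @param scn Scenario template (management and forcings are overridden).
#' @param T Constant temperature, degC.
#' @param f_resid Residual fraction used for the scan.
#' @param cycle_length,max_cycles,tol Passed to
#'   [run_to_periodic_steady_state()].
#' @return Named vector of time-averaged biomass (g COD-B) per group.
#' @export
steady_state_biomass <- function(scn, T, f_resid = 0.95,
                                 cycle_length = 365, max_cycles = 8,
                                 tol = 1e-2) {
  scn$forcings <- forcing_series(0, temp_c = T, ph = 7)
  scn$management <- management_scheme(F_in = scn$management$F_in,
                                      M_max = scn$management$M_max,
                                      f_resid = f_resid,
                                      a_enrich = scn$management$a_enrich)
  scn$duration <- cycle_length
  traj <- run_to_periodic_steady_state(scn, cycle_length, max_cycles, tol)
  st <- traj$states
  xc <- traj$group_state_cols
  w <- diff(st$time)
  mid <- function(v) (v[-1] + v[-length(v)]) / 2
  out <- vapply(xc, function(cn) sum(mid(st[[cn]]) * w) / sum(w), 0)
  stats::setNames(out, sub("^X_", "", xc))
}
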