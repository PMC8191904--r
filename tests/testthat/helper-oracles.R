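# Shared fixtures and independent oracles for the test suite.

# A short default scenario with the shipped parameter set.
quick_scenario <- function(duration = 60, ...) {
  default_scenario(duration = duration, ...)
}

# One-group scenario useful for analytic checks.
one_group_scenario <- function(duration = 20, X_init = NULL,
                               C_X_in = 0.001, k_d = 0.02) {
  g <- microbial_group("m", cardinal_params(0, 35, 45, 7),
                       Y = 0.05, k_d = k_d, C_X_in = C_X_in,
                       X_init = X_init)
  scenario(groups = list(g), duration = duration)
}

# Random admissible reactor state for property sweeps.
random_state <- function(scn, rng) {
  st <- initial_state(scn)
  n <- length(scn$groups)
  st[["M"]] <- rng(1, 5000, 33000)
  st[["Sp"]] <- rng(1, 0, 5e5)
  st[["VFA"]] <- rng(1, 0, 5e4)
  st[["SO4"]] <- rng(1, 0, 5e3)
  st[["sulfide"]] <- rng(1, 0, 500)
  st[["TAN"]] <- rng(1, 0, 1e5)
  st[grep("^X_", names(st))] <- rng(n, 0, 2e3)
  st
}

# Independent Petersen-matrix oracle: assemble the stoichiometric matrix
# explicitly (one row per process) and form the state derivative as
# t(S) %*% rates, taking the process rates from the RHS diagnostics. This
# checks the signed bookkeeping of the RHS, not its rate laws.
petersen_oracle <- function(t, state, scn) {
  out <- slurry_derivatives(t, state, scn)
  ex <- out[[2]]
  ids <- vapply(scn$groups, `[[`, "", "id")
  is_sr <- vapply(scn$groups, `[[`, FALSE, "is_sulfate_reducer")
  Y <- vapply(scn$groups, `[[`, 0, "Y")
  kd <- vapply(scn$groups, `[[`, 0, "k_d")
  pr <- scn$productivities
  P_CH4 <- ifelse(is_sr, 0, (1 - Y) / 4)
  nm <- names(state)
  S <- list()  # named coefficient vectors, one per process
  add <- function(coef) S[[length(S) + 1]] <<- coef
  rates <- numeric(0)
  co <- function(...) {
    v <- stats::setNames(numeric(length(nm)), nm)
    kv <- list(...)
    for (k in names(kv)) v[[k]] <- kv[[k]]
    v
  }
  # hydrolysis
  add(co(Sp = -1, VFA = 1)); rates <- c(rates, ex[["rate_hydrolysis"]])
  # uptake per group
  for (i in seq_along(ids)) {
    xi <- paste0("X_", ids[i])
    if (is_sr[i]) {
      f <- pr$f_CODS_sulfur
      args <- stats::setNames(
        list(-1, -f, f, Y[i], pr$P_CO2_sr),
        c("VFA", "SO4", "sulfide", xi, "CO2_cum"))
      add(do.call(co, args))
    } else {
      args <- stats::setNames(
        list(-1, Y[i], P_CH4[i], pr$P_CO2_anaer),
        c("VFA", xi, "CH4_cum", "CO2_cum"))
      add(do.call(co, args))
    }
    rates <- c(rates, ex[[paste0("uptake_", ids[i])]])
  }
  # surface respiration
  add(co(Sp = -1, CO2_cum = scn$productivities$P_CO2_aer, COD_resp_cum = 1))
  rates <- c(rates, ex[["rate_respiration"]])
  # H2S emission
  add(co(sulfide = -1, H2S_emitted_cum = 1))
  rates <- c(rates, ex[["rate_h2s_emission"]])
  # decay per group
  for (i in seq_along(ids)) {
    args <- stats::setNames(list(-1, 1), c(paste0("X_", ids[i]), "Sp"))
    add(do.call(co, args))
    rates <- c(rates, kd[i] * max(state[[paste0("X_", ids[i])]], 0))
  }
  # inflow
  inf <- scn$influent
  C_X_in <- vapply(scn$groups, `[[`, 0, "C_X_in")
  args <- c(list(M = 1, Sp = inf$C_Sp_in, VFA = inf$C_VFA_in,
                 SO4 = inf$C_SO4_in, sulfide = inf$C_H2S_in,
                 TAN = inf$C_TAN_in,
                 COD_in_cum = inf$C_Sp_in + inf$C_VFA_in + sum(C_X_in) +
                   2 * inf$C_H2S_in,
                 S_in_cum = inf$C_SO4_in + inf$C_H2S_in,
                 TAN_in_cum = inf$C_TAN_in),
            stats::setNames(as.list(C_X_in), paste0("X_", ids)))
  add(do.call(co, args))
  rates <- c(rates, scn$management$F_in)
  Smat <- do.call(rbind, S)
  drop(t(Smat) %*% rates)
}

# Fixed-step explicit-Euler integrator with analytic threshold events;
# independent of the adaptive deSolve path used by simulate_slurry().
euler_simulate <- function(scn, h = 1e-4) {
  ctx <- slurrygas:::build_context(scn)
  forc <- slurrygas:::forcing_functions(scn)
  mgmt <- scn$management
  y <- initial_state(scn)
  t <- 0
  events <- numeric(0)
  while (t < scn$duration - 1e-12) {
    t_event <- t + next_removal_time(y[["M"]], mgmt)
    t_end <- min(t_event, scn$duration)
    nstep <- ceiling((t_end - t) / h)
    for (k in seq_len(nstep)) {
      hk <- min(h, t_end - t)
      y <- y + hk * slurrygas:::reactor_rhs(t, y, ctx, forc)[[1]]
      t <- t + hk
    }
    if (t_event <= scn$duration) {
      rem <- apply_removal(y, mgmt)
      y <- rem$state
      events <- c(events, t)
    }
  }
  list(state = y, events = events)
}
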