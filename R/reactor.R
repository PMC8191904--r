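# Continuous reactor dynamics: state vector layout, air-slurry transfer,
# and the Petersen-matrix right-hand side.
#
# State vector (named, g except M in kg): M, Sp, VFA, SO4, sulfide, TAN,
# X_<id> per group, then the bookkeeping accumulators CH4_cum, CO2_cum,
# H2S_emitted_cum, COD_in_cum, COD_resp_cum, S_in_cum, TAN_in_cum.

#' Influent slurry composition
#'
#' Concentrations in the fresh slurry entering the store, all g per kg
#' slurry (COD basis for organics, elemental basis for S and N). Per-group
#' biomass concentrations live on the [microbial_group()] objects.
#'
#' @param C_Sp_in Degradable particulate material, g COD-S per kg.
#' @param C_VFA_in Volatile fatty acids, g COD-S per kg.
#' @param C_SO4_in Sulfate, g SO4-S per kg.
#' @param C_H2S_in Dissolved sulfide, g S per kg.
#' @param C_TAN_in Total ammoniacal N, g N per kg.
#' @return An object of class `influent_composition`.
#' @export
influent_composition <- function(C_Sp_in = 47.7, C_VFA_in = 1.0,
                                 C_SO4_in = 0.2, C_H2S_in = 0,
                                 C_TAN_in = 2.0) {
  v <- c(C_Sp_in, C_VFA_in, C_SO4_in, C_H2S_in, C_TAN_in)
  if (any(v < 0)) stop("influent concentrations must be >= 0")
  structure(list(C_Sp_in = C_Sp_in, C_VFA_in = C_VFA_in,
                 C_SO4_in = C_SO4_in, C_H2S_in = C_H2S_in,
                 C_TAN_in = C_TAN_in),
            class = "influent_composition")
}

#' Air-slurry transfer parameters
#'
#' Transfer coefficients are expressed as the equivalent slurry mass
#' exchanged with the surface film (kg per m2 per d), so that
#' flux = kL * area * concentration difference (g per kg). The oxygen Henry
#' constant is expressed so that `pO2 / kH_O2` is the saturated dissolved O2
#' concentration in g per kg.
#'
#' @param area Slurry surface area, m2, > 0.
#' @param kL_O2 O2 transfer coefficient, kg per m2 per d.
#' @param kH_O2 O2 Henry constant, atm kg per g.
#' @param kL_H2S H2S transfer coefficient, kg per m2 per d (default from
#'   assuming depletion within a 1 cm surface film turned over daily).
#' @param pO2 Atmospheric O2 mole fraction (0.208).
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(area = 33, kL_O2 = 100, kH_O2 = 24.2,
                            kL_H2S = 10, pO2 = 0.208) {
  if (area <= 0) stop("area must be > 0")
  if (any(c(kL_O2, kH_O2, kL_H2S) < 0)) stop("coefficients must be >= 0")
  structure(list(area = area, kL_O2 = kL_O2, kH_O2 = kH_O2,
                 kL_H2S = kL_H2S, pO2 = pO2),
            class = "transfer_params")
}

#' Surface respiration rate
#'
#' O2-transfer-limited aerobic oxidation of particulate material at the
#' slurry surface; independent of the bulk substrate level (the right-hand
#' side gates it smoothly so it cannot drive the pool negative).
#'
#' @param tp A [transfer_params()] object.
#' @return R, g COD-S per d.
#' @export
surface_respiration <- function(tp) {
  stopifnot(inherits(tp, "transfer_params"))
  tp$kL_O2 * tp$area * (tp$pO2 / tp$kH_O2 - 0)
}

#' Hydrogen sulfide emission rate
#'
#' Proportional to the slurry surface area and to the unionized H2S
#' concentration (zero in air).
#'
#' @param tp A [transfer_params()] object.
#' @param C_H2S Unionized H2S concentration, g S per kg slurry, >= 0.
#' @return Emission rate, g S per d.
#' @export
h2s_emission_rate <- function(tp, C_H2S) {
  stopifnot(inherits(tp, "transfer_params"))
  if (any(C_H2S < 0)) stop("C_H2S must be >= 0")
  tp$kL_H2S * tp$area * (C_H2S - 0)
}

# --- internal: compiled scenario context and state layout ------------------

state_template <- function(group_ids) {
  c("M", "Sp", "VFA", "SO4", "sulfide", "TAN",
    paste0("X_", group_ids),
    "CH4_cum", "CO2_cum", "H2S_emitted_cum",
    "COD_in_cum", "COD_resp_cum", "S_in_cum", "TAN_in_cum")
}

# Flatten the scenario into plain vectors for a fast RHS.
build_context <- function(scenario) {
  g <- scenario$groups
  n <- length(g)
  ids <- vapply(g, `[[`, "", "id")
  num <- function(field) vapply(g, function(x) x[[field]], 0)
  card <- function(field) vapply(g, function(x) x$cardinal[[field]], 0)
  inh <- function(field) vapply(g, function(x) x$inhibition[[field]], 0)
  is_sr <- vapply(g, `[[`, FALSE, "is_sulfate_reducer")
  if (sum(is_sr) > 1)
    stop("at most one sulfate reducer group is supported")
  pr <- scenario$productivities
  P_CH4_i <- if (is.null(pr$P_CH4)) {
    methane_productivity(num("Y"))
  } else rep(pr$P_CH4, n)
  P_CH4_i[is_sr] <- 0
  ks_so4 <- vapply(g, function(x)
    if (is.null(x$KS_SO4)) NA_real_ else x$KS_SO4, 0)
  list(
    n = n, ids = ids, is_sr = is_sr, i_sr = which(is_sr),
    Tmin = card("T_min"), Topt = card("T_opt"), Tmax = card("T_max"),
    qopt = card("rate_opt"),
    Y = num("Y"), kd = num("k_d"), KScoef = num("KS_coef"),
    KS_SO4 = ks_so4, C_X_in = num("C_X_in"),
    pH_LL = inh("pH_LL"), pH_UL = inh("pH_UL"),
    K_NH3 = inh("K_NH3"), K_NH4 = inh("K_NH4"), K_H2S = inh("K_H2S"),
    P_CH4_i = P_CH4_i,
    P_CO2_anaer = pr$P_CO2_anaer, P_CO2_sr = pr$P_CO2_sr,
    P_CO2_aer = pr$P_CO2_aer, f_CODS = pr$f_CODS_sulfur,
    influent = scenario$influent,
    transfer = scenario$transfer,
    hydrolysis = scenario$hydrolysis,
    ks = scenario$ks_params,
    sp = scenario$speciation,
    eps = scenario$solver$gate_eps,
    state_names = state_template(ids),
    iX = 6 + seq_len(n)
  )
}

# CTM1 over the per-group cardinal vectors at scalar temperature T.
ctm1_vec <- function(T, Tmin, Topt, Tmax, ropt) {
  num <- (T - Tmax) * (T - Tmin)^2
  den <- (Topt - Tmin) *
    ((Topt - Tmin) * (T - Topt) - (Topt - Tmax) * (Topt + Tmin - 2 * T))
  r <- ropt * num / den
  r[T <= Tmin | T >= Tmax] <- 0
  pmax(r, 0)
}

# Petersen-matrix right-hand side. `forc` supplies temperature(t), ph(t)
# and F_in(t). Each flux is computed once and reused with matching signed
# coefficients, so linear conservation laws hold to rounding.
reactor_rhs <- function(t, state, ctx, forc) {
  T <- forc$temperature(t)
  pH <- forc$ph(t)
  F_in <- forc$F_in(t)

  M <- max(state[[1]], 1e-9)
  Sp <- max(state[[2]], 0)
  VFA <- max(state[[3]], 0)
  SO4 <- max(state[[4]], 0)
  sulfide <- max(state[[5]], 0)
  TAN <- max(state[[6]], 0)
  X <- pmax(state[ctx$iX], 0)

  C_VFA <- VFA / M
  C_SO4 <- SO4 / M
  tan_frac <- 1 / (1 + 10^(pka_ammonia(T, ctx$sp) - pH))
  C_NH3 <- TAN * tan_frac / M
  C_NH4 <- TAN * (1 - tan_frac) / M
  C_H2S <- sulfide / (1 + 10^(pH - pka_h2s(T, ctx$sp))) / M

  qmax <- ctm1_vec(T, ctx$Tmin, ctx$Topt, ctx$Tmax, ctx$qopt)
  KS <- ctx$KScoef * ctx$ks$k1 * exp(-ctx$ks$k2 * T)
  alpha <- ctm1_vec(T, ctx$hydrolysis$T_min, ctx$hydrolysis$T_opt,
                    ctx$hydrolysis$T_max, ctx$hydrolysis$rate_opt)

  I <- ph_inhibition_factor(pH, ctx$pH_LL, ctx$pH_UL) *
    (1 / (1 + C_NH3 / ctx$K_NH3)) *
    (1 / (1 + C_NH4 / ctx$K_NH4)) *
    (1 / (1 + C_H2S / ctx$K_H2S))
  I <- pmin(pmax(I, 0), 1)

  r <- qmax * C_VFA / (KS + C_VFA) * X * I
  if (length(ctx$i_sr))
    r[ctx$i_sr] <- r[ctx$i_sr] * C_SO4 / (ctx$KS_SO4[ctx$i_sr] + C_SO4)

  hyd <- alpha * Sp
  decay <- ctx$kd * X
  tp <- ctx$transfer
  R_resp <- tp$kL_O2 * tp$area * (tp$pO2 / tp$kH_O2) * Sp / (Sp + ctx$eps)
  E_h2s <- tp$kL_H2S * tp$area * C_H2S

  r_sr <- if (length(ctx$i_sr)) r[ctx$i_sr] else 0
  r_meth_sum <- sum(r) - r_sr

  inf <- ctx$influent
  d <- numeric(length(state))
  d[1] <- F_in
  d[2] <- -hyd - R_resp + sum(decay) + F_in * inf$C_Sp_in
  d[3] <- hyd - sum(r) + F_in * inf$C_VFA_in
  d[4] <- -ctx$f_CODS * r_sr + F_in * inf$C_SO4_in
  d[5] <- ctx$f_CODS * r_sr - E_h2s + F_in * inf$C_H2S_in
  d[6] <- F_in * inf$C_TAN_in
  d[ctx$iX] <- ctx$Y * r - decay + F_in * ctx$C_X_in
  nX <- ctx$n
  dCH4 <- sum(ctx$P_CH4_i * r)
  d[7 + nX] <- dCH4                                          # CH4_cum
  d[8 + nX] <- ctx$P_CO2_anaer * r_meth_sum + ctx$P_CO2_sr * r_sr +
    ctx$P_CO2_aer * R_resp                                   # CO2_cum
  d[9 + nX] <- E_h2s                                         # H2S_emitted_cum
  d[10 + nX] <- F_in * (inf$C_Sp_in + inf$C_VFA_in + sum(ctx$C_X_in) +
                          2 * inf$C_H2S_in)                  # COD_in_cum
  d[11 + nX] <- R_resp                                       # COD_resp_cum
  d[12 + nX] <- F_in * (inf$C_SO4_in + inf$C_H2S_in)         # S_in_cum
  d[13 + nX] <- F_in * inf$C_TAN_in                          # TAN_in_cum

  extras <- c(rate_hydrolysis = hyd,
              stats::setNames(r, paste0("uptake_", ctx$ids)),
              stats::setNames(I, paste0("I_", ctx$ids)),
              rate_respiration = R_resp, rate_h2s_emission = E_h2s,
              rate_decay_total = sum(decay), rate_CH4 = dCH4,
              temp_c = T, ph = pH)
  list(d, extras)
}

#' Time derivative of the reactor state
#'
#' Evaluates the full Petersen-matrix right-hand side (hydrolysis, per-group
#' uptake, sulfate reduction, surface respiration, H2S emission, decay
#' recycling, inflow) at one instant. Mainly useful for inspection and for
#' building independent integration oracles; [simulate_slurry()] uses the
#' same core.
#'
#' @param t Time (d).
#' @param state Named state vector as produced by [initial_state()].
#' @param scenario A [scenario()] object.
#' @return A list: the derivative vector, and a named vector of per-process
#'   rates and inhibition factors.
#' @export
slurry_derivatives <- function(t, state, scenario) {
  ctx <- build_context(scenario)
  forc <- forcing_functions(scenario)
  out <- reactor_rhs(t, state, ctx, forc)
  names(out[[1]]) <- ctx$state_names
  out
}
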