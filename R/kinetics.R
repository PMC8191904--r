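# Temperature, substrate and inhibition responses for all biological rates.
# Units: temperature degC, time d, substrate g COD-S, biomass g COD-B,
# concentrations g per kg slurry.

#' Cardinal temperature parameters
#'
#' Bundles the three cardinal temperatures and the rate at the optimum for a
#' CTM1 temperature response. Used both for the maximum specific substrate
#' utilization rate of a microbial group (`rate_opt` = q_max,opt) and for the
#' hydrolysis rate constant (`rate_opt` = alpha_opt).
#'
#' @param T_min,T_opt,T_max Cardinal temperatures (degC), `T_min < T_opt < T_max`.
#' @param rate_opt Rate at `T_opt` (units of the governed rate), >= 0.
#' @return An object of class `cardinal_params`.
#' @seealso [cardinal_rate()]
#' @export
cardinal_params <- function(T_min, T_opt, T_max, rate_opt) {
  stopifnot(is.numeric(T_min), is.numeric(T_opt), is.numeric(T_max),
            is.numeric(rate_opt), length(rate_opt) == length(T_opt))
  if (any(!(T_min < T_opt & T_opt < T_max)))
    stop("cardinal temperatures must satisfy T_min < T_opt < T_max")
  if (any(rate_opt < 0)) stop("rate_opt must be >= 0")
  structure(list(T_min = T_min, T_opt = T_opt, T_max = T_max,
                 rate_opt = rate_opt),
            class = "cardinal_params")
}

#' CTM1 rate at a given temperature
#'
#' Cardinal Temperature Model 1: the rate is `rate_opt` at `T_opt`, falls to
#' zero at `T_min` and `T_max`, and is clamped to exactly zero outside the
#' open interval (`T_min`, `T_max`) -- no biological activity beyond the
#' cardinal limits.
#'
#' @param T Temperature (degC); vectorized.
#' @param p A [cardinal_params()] object (fields may be vectors of common
#'   length when `T` is scalar, giving one rate per parameter set).
#' @return Rate(s) in the units of `p$rate_opt`.
#' @export
cardinal_rate <- function(T, p) {
  stopifnot(inherits(p, "cardinal_params"))
  num <- (T - p$T_max) * (T - p$T_min)^2
  den <- (p$T_opt - p$T_min) *
    ((p$T_opt - p$T_min) * (T - p$T_opt) -
       (p$T_opt - p$T_max) * (p$T_opt + p$T_min - 2 * T))
  r <- p$rate_opt * num / den
  r[T <= p$T_min | T >= p$T_max] <- 0
  pmax(r, 0)
}

#' Shared temperature dependence of the Monod half-saturation constant
#'
#' @param k1 Half-saturation constant at 0 degC (g COD-S per kg slurry), > 0.
#' @param k2 Exponential temperature coefficient (per degC), > 0.
#' @return An object of class `ks_temperature_params`.
#' @export
ks_temperature_params <- function(k1, k2) {
  if (!is.numeric(k1) || k1 <= 0) stop("k1 must be > 0")
  if (!is.numeric(k2) || k2 <= 0) stop("k2 must be > 0")
  structure(list(k1 = k1, k2 = k2), class = "ks_temperature_params")
}

#' Half-saturation constant at temperature
#'
#' K_S decreases exponentially with temperature; a dimensionless per-group
#' multiplier `KS_coef` (default 1) rescales the shared curve to reflect
#' differences in substrate affinity among groups.
#'
#' @param T Temperature (degC); vectorized.
#' @param KS_coef Dimensionless multiplier, > 0.
#' @param p A [ks_temperature_params()] object.
#' @return K_S in g COD-S per kg slurry.
#' @export
ks_at_temperature <- function(T, KS_coef = 1, p) {
  stopifnot(inherits(p, "ks_temperature_params"))
  if (any(KS_coef <= 0)) stop("KS_coef must be > 0")
  KS_coef * p$k1 * exp(-p$k2 * T)
}

#' Default maximum utilization rate from the optimum temperature
#'
#' Assigns q_max,opt by the linear rule: 0 at 0 degC rising to
#' `anchor_rate` at `anchor_T`, extrapolated linearly above the anchor.
#'
#' @param T_opt Optimum temperature of the group (degC), >= 0.
#' @param anchor_T Anchor temperature (degC), default 40.
#' @param anchor_rate Rate at the anchor (g COD-S per g COD-B per d), default 8.
#' @return q_max,opt in g COD-S per g COD-B per d.
#' @export
qmax_opt_from_linear_rule <- function(T_opt, anchor_T = 40, anchor_rate = 8) {
  if (any(T_opt < 0)) stop("T_opt must be >= 0")
  anchor_rate * T_opt / anchor_T
}

#' Per-group inhibition constants
#'
#' The pH response is an ADM1-style normalized bell over
#' (`pH_LL`, `pH_UL`) equal to 1 at the midpoint optimum; NH3, NH4+ and H2S
#' act noncompetitively, `I = 1 / (1 + C / K_I)`.
#'
#' @param pH_LL,pH_UL Lower/upper pH bounds of activity.
#' @param K_NH3 Free-ammonia inhibition constant (g N per kg slurry).
#' @param K_NH4 Ammonium inhibition constant (g N per kg slurry).
#' @param K_H2S Unionized hydrogen sulfide inhibition constant
#'   (g S per kg slurry).
#' @return An object of class `inhibition_constants`.
#' @export
inhibition_constants <- function(pH_LL = 6.0, pH_UL = 8.5,
                                 K_NH3 = 0.025, K_NH4 = 10, K_H2S = 0.15) {
  if (pH_LL >= pH_UL) stop("pH_LL must be < pH_UL")
  if (any(c(K_NH3, K_NH4, K_H2S) <= 0)) stop("inhibition constants must be > 0")
  structure(list(pH_LL = pH_LL, pH_UL = pH_UL,
                 K_NH3 = K_NH3, K_NH4 = K_NH4, K_H2S = K_H2S),
            class = "inhibition_constants")
}

# Normalized bell pH limitation; exactly 1 at the midpoint of (LL, UL).
ph_inhibition_factor <- function(pH, pH_LL, pH_UL) {
  num <- 1 + 2 * 10^(0.5 * (pH_LL - pH_UL))
  den <- 1 + 10^(pH - pH_UL) + 10^(pH_LL - pH)
  pmin(pmax(num / den, 0), 1)
}

noncompetitive_factor <- function(C, K_I) {
  pmin(pmax(1 / (1 + pmax(C, 0) / K_I), 0), 1)
}

#' One microbial population (methanogen or sulfate reducer)
#'
#' @param id Short label, e.g. `"m3"` or `"sr1"`.
#' @param cardinal A [cardinal_params()] whose `rate_opt` is q_max,opt
#'   (g COD-S per g COD-B per d). If `rate_opt` is `NA`, it is filled from
#'   [qmax_opt_from_linear_rule()] applied to `T_opt`.
#' @param Y Biomass yield (g COD-B per g COD-S), in (0, 1).
#' @param k_d First-order decay rate (per d), >= 0.
#' @param KS_coef Dimensionless half-saturation multiplier, > 0.
#' @param KS_SO4 Sulfate half-saturation (g SO4-S per kg slurry); required
#'   for sulfate reducers, ignored otherwise.
#' @param inhibition An [inhibition_constants()] object.
#' @param C_X_in Active-biomass concentration in the influent slurry
#'   (g COD-B per kg slurry), >= 0.
#' @param X_init Initial biomass (g COD-B); `NULL` means "derive from the
#'   initial slurry mass and `C_X_in`" when the scenario is assembled.
#' @param is_sulfate_reducer Logical flag.
#' @return An object of class `microbial_group`.
#' @export
microbial_group <- function(id, cardinal, Y = 0.05, k_d = 0.02,
                            KS_coef = 1, KS_SO4 = NULL,
                            inhibition = inhibition_constants(),
                            C_X_in = 0.001, X_init = NULL,
                            is_sulfate_reducer = FALSE) {
  stopifnot(inherits(cardinal, "cardinal_params"),
            inherits(inhibition, "inhibition_constants"))
  if (is.na(cardinal$rate_opt))
    cardinal$rate_opt <- qmax_opt_from_linear_rule(cardinal$T_opt)
  if (!(Y > 0 && Y < 1)) stop("Y must be in (0, 1)")
  if (k_d < 0) stop("k_d must be >= 0")
  if (KS_coef <= 0) stop("KS_coef must be > 0")
  if (C_X_in < 0) stop("C_X_in must be >= 0")
  if (is_sulfate_reducer && (is.null(KS_SO4) || KS_SO4 <= 0))
    stop("a sulfate reducer needs KS_SO4 > 0")
  structure(list(id = id, cardinal = cardinal, Y = Y, k_d = k_d,
                 KS_coef = KS_coef, KS_SO4 = KS_SO4,
                 inhibition = inhibition, C_X_in = C_X_in, X_init = X_init,
                 is_sulfate_reducer = isTRUE(is_sulfate_reducer)),
            class = "microbial_group")
}

#' Monod substrate uptake rate of a methanogen group
#'
#' Returns the VFA consumption magnitude (g COD-S per d); the reactor module
#' applies signs per the process stoichiometry.
#'
#' @param C_VFA VFA concentration (g COD-S per kg slurry), >= 0.
#' @param K_S Half-saturation constant (g COD-S per kg slurry), > 0.
#' @param q_max Maximum specific utilization rate at the current temperature
#'   (g COD-S per g COD-B per d), >= 0.
#' @param X Active biomass (g COD-B), >= 0.
#' @param I_product Combined inhibition factor in `[0, 1]`.
#' @return Uptake rate, g COD-S per d.
#' @export
methanogen_uptake_rate <- function(C_VFA, K_S, q_max, X, I_product = 1) {
  if (any(I_product < 0 | I_product > 1))
    stop("I_product must lie in [0, 1]")
  q_max * C_VFA / (K_S + C_VFA) * X * I_product
}

#' Double-Monod uptake rate of the sulfate reducer
#'
#' As [methanogen_uptake_rate()] with an additional Monod limitation in the
#' sulfate electron acceptor.
#'
#' @inheritParams methanogen_uptake_rate
#' @param C_SO4 Sulfate concentration (g SO4-S per kg slurry), >= 0.
#' @param K_S_SO4 Sulfate half-saturation (g SO4-S per kg slurry), > 0.
#' @param X_sr Sulfate-reducer biomass (g COD-B), >= 0.
#' @return Uptake rate, g COD-S per d.
#' @export
sulfate_reduction_rate <- function(C_VFA, C_SO4, K_S, K_S_SO4, q_max, X_sr,
                                   I_product = 1) {
  if (any(I_product < 0 | I_product > 1))
    stop("I_product must lie in [0, 1]")
  q_max * C_VFA / (K_S + C_VFA) * C_SO4 / (K_S_SO4 + C_SO4) * X_sr * I_product
}

#' Combined inhibition factor of one group
#'
#' Product of the pH, free-ammonia, ammonium and hydrogen sulfide factors,
#' each in `[0, 1]`.
#'
#' @param pH Slurry pH.
#' @param C_NH3,C_NH4 Free ammonia / ammonium N concentration
#'   (g N per kg slurry), >= 0.
#' @param C_H2S Unionized hydrogen sulfide concentration (g S per kg slurry),
#'   >= 0.
#' @param g A [microbial_group()] (its `inhibition` constants are used).
#' @return A value in `[0, 1]`.
#' @export
inhibition_product <- function(pH, C_NH3, C_NH4, C_H2S, g) {
  ic <- if (inherits(g, "microbial_group")) g$inhibition else g
  stopifnot(inherits(ic, "inhibition_constants"))
  I <- ph_inhibition_factor(pH, ic$pH_LL, ic$pH_UL) *
    noncompetitive_factor(C_NH3, ic$K_NH3) *
    noncompetitive_factor(C_NH4, ic$K_NH4) *
    noncompetitive_factor(C_H2S, ic$K_H2S)
  pmin(pmax(I, 0), 1)
}

#' Speciation constants
#'
#' Reference pKa values at 25 degC and van 't Hoff enthalpies governing their
#' temperature dependence, for the NH4+/NH3 and H2S/HS- equilibria. All
#' config-exposed.
#'
#' @param pKa_NH4_A,pKa_NH4_B NH4+ acidity: pKa(T) = A + B / T_K
#'   (Emerson-type relation).
#' @param pKa_H2S_25 First H2S acidity constant at 25 degC.
#' @param dH_H2S Dissociation enthalpy of H2S (J per mol) for the van 't Hoff
#'   adjustment.
#' @return An object of class `speciation_params`.
#' @export
speciation_params <- function(pKa_NH4_A = 0.09018, pKa_NH4_B = 2729.92,
                              pKa_H2S_25 = 7.02, dH_H2S = 22100) {
  structure(list(pKa_NH4_A = pKa_NH4_A, pKa_NH4_B = pKa_NH4_B,
                 pKa_H2S_25 = pKa_H2S_25, dH_H2S = dH_H2S),
            class = "speciation_params")
}

pka_ammonia <- function(T, sp = speciation_params()) {
  sp$pKa_NH4_A + sp$pKa_NH4_B / (T + 273.15)
}

pka_h2s <- function(T, sp = speciation_params()) {
  R <- 8.314
  sp$pKa_H2S_25 + sp$dH_H2S / (R * log(10)) * (1 / (T + 273.15) - 1 / 298.15)
}

#' Speciate total ammoniacal nitrogen
#'
#' Splits TAN into free ammonia and ammonium at the given pH and temperature;
#' the two fractions sum exactly to the input.
#'
#' @param TAN Total ammoniacal N (g N).
#' @param pH Slurry pH.
#' @param T Temperature (degC).
#' @param sp A [speciation_params()] object.
#' @return Named list with elements `NH3` and `NH4` (g N).
#' @export
speciate_tan <- function(TAN, pH, T, sp = speciation_params()) {
  if (any(TAN < 0)) stop("TAN must be >= 0")
  f_nh3 <- 1 / (1 + 10^(pka_ammonia(T, sp) - pH))
  NH3 <- TAN * f_nh3
  list(NH3 = NH3, NH4 = TAN - NH3)
}

#' Unionized hydrogen sulfide concentration
#'
#' @param S_total Total dissolved sulfide (g S).
#' @param pH Slurry pH.
#' @param T Temperature (degC).
#' @param slurry_mass Slurry mass (kg), > 0.
#' @param sp A [speciation_params()] object.
#' @return Unionized H2S concentration, g S per kg slurry.
#' @export
speciate_sulfide <- function(S_total, pH, T, slurry_mass,
                             sp = speciation_params()) {
  if (any(S_total < 0)) stop("S_total must be >= 0")
  if (any(slurry_mass <= 0))
    stop("slurry mass must be > 0 to form a concentration")
  f_h2s <- 1 / (1 + 10^(pH - pka_h2s(T, sp)))
  S_total * f_h2s / slurry_mass
}
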