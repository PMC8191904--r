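# Productivity coefficients, VS <-> COD conversion, COD-balance auditing.
# COD is the conserved currency: CH4 carries 4 g COD per g, sulfide 2 g COD
# per g S (H2S + 2 O2 -> SO4), CO2 carries none.

COD_PER_G_CH4 <- 4
COD_PER_G_SULFIDE_S <- 2

#' Methane productivity coefficient
#'
#' Substrate COD not incorporated into biomass leaves as methane at
#' 4 g COD per g CH4, so `P_CH4 = (1 - Y) / 4`.
#'
#' @param Y Biomass yield (g COD-B per g COD-S), in (0, 1).
#' @return g CH4 per g COD-S consumed.
#' @export
methane_productivity <- function(Y) {
  if (any(Y <= 0 | Y >= 1)) stop("Y must be in (0, 1)")
  (1 - Y) / COD_PER_G_CH4
}

#' Gas productivity coefficients
#'
#' CO2 productivities for the anaerobic pathway (fermentation plus
#' methanogenesis combined -- accurate at steady state or as a cumulative
#' response, less so during VFA accumulation), for sulfate reduction, and
#' for aerobic surface respiration, together with the sulfur conversion
#' factor of sulfate reduction. Defaults assume an acetate-like substrate
#' (64 g COD, 44 g CO2 + 16 g CH4 per mol when Y = 0) and glucose-like
#' aerobic combustion (264 g CO2 per 192 g COD). `f_CODS_sulfur` defaults to
#' the yield-corrected electron balance `(1 - Y_sr) / 2` g SO4-S reduced per
#' g COD-S consumed, which makes the reactor right-hand side exactly
#' COD-conserving.
#'
#' @param Y Methanogen yield used for the anaerobic coefficient.
#' @param Y_sr Sulfate-reducer yield used for the sulfate-reduction
#'   coefficient and `f_CODS_sulfur`.
#' @param P_CH4,P_CO2_anaer,P_CO2_sr,P_CO2_aer,f_CODS_sulfur Optional
#'   overrides of the individual coefficients.
#' @return An object of class `productivities` with fields `P_CH4`
#'   (g CH4 per g COD-S), `P_CO2_anaer`, `P_CO2_sr`, `P_CO2_aer`
#'   (g CO2 per g COD-S) and `f_CODS_sulfur` (g S per g COD-S).
#' @export
co2_productivities <- function(Y = 0.05, Y_sr = 0.08,
                               P_CH4 = NULL, P_CO2_anaer = NULL,
                               P_CO2_sr = NULL, P_CO2_aer = NULL,
                               f_CODS_sulfur = NULL) {
  if (any(Y <= 0 | Y >= 1)) stop("Y must be in (0, 1)")
  p <- list(
    P_CH4         = if (is.null(P_CH4)) methane_productivity(Y) else P_CH4,
    P_CO2_anaer   = if (is.null(P_CO2_anaer)) (1 - Y) * 44 / 64 else P_CO2_anaer,
    P_CO2_sr      = if (is.null(P_CO2_sr)) (1 - Y_sr) * 88 / 64 else P_CO2_sr,
    P_CO2_aer     = if (is.null(P_CO2_aer)) 264 / 192 else P_CO2_aer,
    f_CODS_sulfur = if (is.null(f_CODS_sulfur)) (1 - Y_sr) / 2 else f_CODS_sulfur
  )
  if (any(unlist(p) < 0)) stop("productivities must be >= 0")
  structure(p, class = "productivities")
}

#' @rdname co2_productivities
#' @export
productivities <- co2_productivities

#' VS-to-COD conversion parameters
#'
#' @param f_degradable Fraction of volatile solids that is degradable,
#'   in `[0, 1]`; default 0.42 for cattle slurry.
#' @param cod_per_vs COD-to-VS ratio (g COD per g VS), > 0; default 1.42
#'   for cattle slurry.
#' @return An object of class `vs_conversion`.
#' @export
vs_conversion <- function(f_degradable = 0.42, cod_per_vs = 1.42) {
  if (f_degradable < 0 || f_degradable > 1)
    stop("f_degradable must be in [0, 1]")
  if (cod_per_vs <= 0) stop("cod_per_vs must be > 0")
  structure(list(f_degradable = f_degradable, cod_per_vs = cod_per_vs),
            class = "vs_conversion")
}

#' Convert volatile solids to degradable particulate COD
#'
#' @param VS Volatile solids mass (g), >= 0.
#' @param conv A [vs_conversion()] object.
#' @return Degradable particulate material, g COD-S.
#' @export
vs_to_degradable_cod <- function(VS, conv = vs_conversion()) {
  if (any(VS < 0)) stop("VS must be >= 0")
  VS * conv$f_degradable * conv$cod_per_vs
}

#' Audit the COD balance of a trajectory
#'
#' Relative residual of the full COD book: influent plus initial COD against
#' stored, removed, emitted (methane at 4 g COD per g, sulfide at 2 g COD
#' per g S) and aerobically respired COD. Zero up to solver rounding for any
#' faithful simulation; a large value flags an integration or bookkeeping
#' defect.
#'
#' @param trajectory A `slurry_trajectory` from [simulate_slurry()].
#' @return Relative residual (dimensionless, >= 0).
#' @export
cod_balance <- function(trajectory) {
  stopifnot(inherits(trajectory, "slurry_trajectory"))
  st <- trajectory$states
  ev <- trajectory$events
  if (is.null(ev)) stop("trajectory lacks an event log")
  xcols <- trajectory$group_state_cols
  first <- st[1, ]
  last <- st[nrow(st), ]
  cod_of <- function(row)
    row$Sp + row$VFA + sum(unlist(row[xcols])) +
      COD_PER_G_SULFIDE_S * row$sulfide
  cod_initial <- cod_of(first)
  cod_in <- last$COD_in_cum - first$COD_in_cum
  cod_stored <- cod_of(last)
  cod_removed <- if (nrow(ev)) {
    sum(ev$removed_Sp + ev$removed_VFA + ev$removed_X +
          COD_PER_G_SULFIDE_S * ev$removed_sulfide)
  } else 0
  cod_emitted <- COD_PER_G_CH4 * (last$CH4_cum - first$CH4_cum) +
    COD_PER_G_SULFIDE_S * (last$H2S_emitted_cum - first$H2S_emitted_cum)
  cod_resp <- last$COD_resp_cum - first$COD_resp_cum
  abs(cod_in + cod_initial - cod_stored - cod_removed - cod_emitted -
        cod_resp) / (cod_in + cod_initial)
}
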