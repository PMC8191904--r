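# Shipped default parameter set ("paper-defaults" in the config layer).
#
# Main-text values: yields (0.05), alpha_opt 0.02 1/d with cardinal
# temperatures (0, 50, 60), the linear q_max,opt rule (8 at 40 degC),
# influent biomass 0.01 g/kg for m3 vs 0.001 for the others, management
# F_in 1000 kg/d, M_max 33333 kg, f_resid 0.1, T 20 degC, pH 7, VS
# conversion 0.42 / 1.42. Per-group cardinal temperatures, Eq-13 constants,
# transfer coefficients and inhibition constants are literature-informed
# placeholders (tagged `provenance: placeholder` in the YAML config) chosen
# to match the named species' growth ranges.

#' Default microbial community
#'
#' Five methanogen groups spanning the psychrophilic to thermophilic range
#' -- m1 (cold-adapted, after *Methanolobus psychrophilus*), m2
#' (intermediate), m3 (mesophilic, after
#' *Methanobrevibacter*/*Methanocorpusculum*; ten-fold higher influent
#' abundance, reflecting its dominance in fresh excreta), m4 (optimum
#' midway between m3 and m5) and m5 (thermophilic, after *Methanosarcina
#' thermophila*) -- plus an optional sulfate reducer sr1 with double-Monod
#' kinetics, higher yield and maximum rate, and stronger substrate affinity.
#' q_max,opt of every group comes from [qmax_opt_from_linear_rule()]
#' (sr1 scaled up 1.2x).
#'
#' @param include_sulfate_reducer Add the sr1 group?
#' @return List of [microbial_group()] objects.
#' @export
default_groups <- function(include_sulfate_reducer = FALSE) {
  mg <- function(id, T_min, T_opt, T_max, C_X_in = 0.001)
    microbial_group(id,
                    cardinal_params(T_min, T_opt, T_max,
                                    qmax_opt_from_linear_rule(T_opt)),
                    Y = 0.05, k_d = 0.02, KS_coef = 1, C_X_in = C_X_in)
  g <- list(
    mg("m1", -2, 18.0, 25),
    mg("m2",  0, 28.0, 38),
    mg("m3", 10, 37.0, 45, C_X_in = 0.01),
    mg("m4", 15, 43.5, 52),
    mg("m5", 20, 50.0, 58)
  )
  if (include_sulfate_reducer) {
    g <- c(g, list(microbial_group(
      "sr1",
      cardinal_params(5, 38, 48, 1.2 * qmax_opt_from_linear_rule(38)),
      Y = 0.08, k_d = 0.02, KS_coef = 0.5, KS_SO4 = 0.02,
      inhibition = inhibition_constants(K_H2S = 0.55),
      C_X_in = 0.001, is_sulfate_reducer = TRUE)))
  }
  g
}

#' Default scenario
#'
#' The default slurry-channel scenario: fresh excreta at 1000 kg/d into a
#' 33333 kg store emptied to a 10% residual when full (a 30-d cadence),
#' constant 20 degC and pH 7, the five-group default community, and
#' first-order hydrolysis at alpha_opt = 0.02 1/d with cardinal
#' temperatures (0, 50, 60).
#'
#' @param duration Simulated time, d.
#' @param include_sulfate_reducer Include sr1?
#' @param ... Overrides passed on to [scenario()].
#' @return A [scenario()] object.
#' @export
default_scenario <- function(duration = 365, include_sulfate_reducer = FALSE,
                             ...) {
  scenario(groups = default_groups(include_sulfate_reducer),
           duration = duration, ...)
}
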