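# Discrete slurry-management events: threshold-triggered emptying, residual
# retention, and biofilm-mediated microbial enrichment.

#' Slurry management scheme
#'
#' @param F_in Slurry production (filling) rate, kg per d, >= 0. Must be a
#'   single constant in `threshold` mode (the event time is then exact).
#' @param M_max Storage capacity, kg, > 0.
#' @param f_resid Fraction of slurry retained at each emptying, in (0, 1).
#' @param a_enrich Microbial enrichment factor: the log-odds increment of
#'   retention for organisms relative to conservative components; 0 means
#'   no enrichment.
#' @param mode `"threshold"` (empty exactly when mass reaches `M_max`),
#'   `"scheduled"` (empty at `times`), or `"forced-mass"` (follow an observed
#'   slurry-mass series supplied in the scenario forcings; decreases become
#'   removal events, increases become filling).
#' @param times Event times (d) for `scheduled` mode.
#' @return An object of class `management_scheme`.
#' @export
management_scheme <- function(F_in = 1000, M_max = 33333, f_resid = 0.1,
                              a_enrich = 0,
                              mode = c("threshold", "scheduled", "forced-mass"),
                              times = NULL) {
  mode <- match.arg(mode)
  if (!(f_resid > 0 && f_resid < 1)) stop("f_resid must be in (0, 1)")
  if (M_max <= 0) stop("M_max must be > 0")
  if (any(F_in < 0)) stop("F_in must be >= 0")
  if (mode == "threshold" && length(F_in) != 1)
    stop("threshold mode requires a constant F_in")
  if (mode == "scheduled" && is.null(times))
    stop("scheduled mode requires event times")
  structure(list(F_in = F_in, M_max = M_max, f_resid = f_resid,
                 a_enrich = a_enrich, mode = mode, times = times),
            class = "management_scheme")
}

#' Biomass retention fraction under enrichment
#'
#' The fraction of a microbial population retained at emptying: the bulk
#' retention odds `f_resid / (1 - f_resid)` are increased by `a_enrich` on
#' the log-odds scale. Equals `f_resid` when `a_enrich = 0`.
#'
#' @param f_resid Bulk residual fraction, in (0, 1) strictly.
#' @param a_enrich Log-odds increment (dimensionless).
#' @return Retention fraction in (0, 1).
#' @export
retention_fraction <- function(f_resid, a_enrich) {
  if (any(f_resid <= 0 | f_resid >= 1))
    stop("f_resid must lie strictly inside (0, 1): logit undefined at 0/1")
  stats::plogis(stats::qlogis(f_resid) + a_enrich)
}

#' Apply an instantaneous removal event
#'
#' Slurry mass and the transported pools (particulate COD, VFA, sulfate,
#' sulfide, TAN) are scaled by `f_resid`; each biomass pool is scaled by its
#' enrichment-adjusted [retention_fraction()]. Cumulative emission and
#' bookkeeping counters are unchanged. Concentrations of conservative
#' solutes are therefore unchanged across the event when `a_enrich = 0`.
#'
#' @param state Named state vector (see [initial_state()]).
#' @param scheme A [management_scheme()]; `f_override` replaces its
#'   `f_resid` for this event (used in forced-mass mode).
#' @param f_override Optional event-specific residual fraction.
#' @return List with `state` (post-event vector) and `removed` (named vector
#'   of removed masses: `M`, `Sp`, `VFA`, `SO4`, `sulfide`, `TAN`, total `X`,
#'   plus per-group entries), and the retention fractions used.
#' @export
apply_removal <- function(state, scheme, f_override = NULL) {
  stopifnot(inherits(scheme, "management_scheme"))
  if (state[["M"]] <= 0) stop("cannot remove from an empty store")
  f <- if (is.null(f_override)) scheme$f_resid else f_override
  if (!(f > 0 && f < 1)) stop("residual fraction must be in (0, 1)")
  fX <- retention_fraction(f, scheme$a_enrich)
  nm <- names(state)
  xi <- grep("^X_", nm)
  bulk <- c("M", "Sp", "VFA", "SO4", "sulfide", "TAN")
  removed <- c(state[bulk] * (1 - f),
               stats::setNames(sum(state[xi]) * (1 - fX), "X"),
               state[xi] * (1 - fX))
  out <- state
  out[bulk] <- state[bulk] * f
  out[xi] <- state[xi] * fX
  list(state = out, removed = removed, f_resid = f, f_resid_X = fX)
}

#' Time until the next threshold-triggered removal
#'
#' With constant filling, the store reaches capacity after exactly
#' `(M_max - M) / F_in` days.
#'
#' @param M Current slurry mass, kg.
#' @param scheme A [management_scheme()] in threshold mode.
#' @return Days until the event; `Inf` when `F_in = 0` (never triggers).
#' @export
next_removal_time <- function(M, scheme) {
  stopifnot(inherits(scheme, "management_scheme"))
  if (scheme$F_in <= 0) return(Inf)
  max((scheme$M_max - M) / scheme$F_in, 0)
}
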