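# YAML scenario configuration, forcing tables, trajectory output.
# Units are fixed at the model's native units (kg slurry, g COD, degC, d);
# no automatic unit conversion.

config_schema <- list(
  top = c("version", "defaults", "duration", "output_dt", "n_warmup_cycles",
          "include_sulfate_reducer", "groups", "hydrolysis", "ks_params",
          "influent", "management", "transfer", "productivities",
          "speciation", "solver", "forcings", "vs_conversion", "provenance"),
  group = c("id", "T_min", "T_opt", "T_max", "qmax_opt", "yield", "k_d",
            "KS_coef", "KS_SO4", "C_X_in", "X_init", "is_sulfate_reducer",
            "inhibition", "provenance"),
  inhibition = c("pH_LL", "pH_UL", "K_NH3", "K_NH4", "K_H2S", "provenance"),
  hydrolysis = c("T_min", "T_opt", "T_max", "alpha_opt", "provenance"),
  ks_params = c("k1", "k2", "provenance"),
  influent = c("C_Sp_in", "C_VFA_in", "C_SO4_in", "C_H2S_in", "C_TAN_in",
               "provenance"),
  management = c("F_in", "M_max", "f_resid", "a_enrich", "mode", "times",
                 "provenance"),
  transfer = c("area", "kL_O2", "kH_O2", "kL_H2S", "pO2", "provenance"),
  productivities = c("P_CH4", "P_CO2_anaer", "P_CO2_sr", "P_CO2_aer",
                     "f_CODS_sulfur", "provenance"),
  speciation = c("pKa_NH4_A", "pKa_NH4_B", "pKa_H2S_25", "dH_H2S",
                 "provenance"),
  solver = c("method", "rtol", "atol", "hmax", "gate_eps", "provenance"),
  forcings = c("times", "temp_c", "ph", "slurry_mass", "provenance"),
  vs_conversion = c("f_degradable", "cod_per_vs", "provenance")
)

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      errs <<- c(errs, paste0("unknown key(s) in ", where, ": ",
                              paste(bad, collapse = ", "),
                              " (allowed: ", paste(allowed, collapse = ", "),
                              ")"))
  }
  chk(cfg, config_schema$top, "top level")
  for (blk in c("hydrolysis", "ks_params", "influent", "management",
                "transfer", "productivities", "speciation", "solver",
                "forcings", "vs_conversion"))
    if (!is.null(cfg[[blk]])) chk(cfg[[blk]], config_schema[[blk]], blk)
  if (!is.null(cfg$groups)) {
    for (i in seq_along(cfg$groups)) {
      chk(cfg$groups[[i]], config_schema$group, paste0("groups[", i, "]"))
      if (!is.null(cfg$groups[[i]]$inhibition))
        chk(cfg$groups[[i]]$inhibition, config_schema$inhibition,
            paste0("groups[", i, "]$inhibition"))
    }
  }
  m <- cfg$management
  if (!is.null(m$f_resid) && !(m$f_resid > 0 && m$f_resid < 1))
    errs <- c(errs, "management$f_resid must be in (0, 1) (dimensionless)")
  if (!is.null(m$M_max) && m$M_max <= 0)
    errs <- c(errs, "management$M_max must be > 0 (kg)")
  if (!is.null(m$F_in) && any(m$F_in < 0))
    errs <- c(errs, "management$F_in must be >= 0 (kg per d)")
  if (!is.null(cfg$duration) && cfg$duration <= 0)
    errs <- c(errs, "duration must be > 0 (d)")
  f <- cfg$forcings
  if (!is.null(f$times) && length(f$times) > 1 && any(diff(f$times) <= 0))
    errs <- c(errs, "forcings$times must be strictly increasing (d)")
  if (length(errs))
    stop("invalid scenario config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

strip_prov <- function(x) {
  x$provenance <- NULL
  x
}

paper_defaults_path <- function() {
  system.file("extdata", "paper-defaults.yaml", package = "slurrygas",
              mustWork = TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (nm %in% c("groups", "forcings")) {
      base[[nm]] <- override[[nm]]      # replaced wholesale
    } else if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

group_from_config <- function(gc) {
  inh <- do.call(inhibition_constants,
                 strip_prov(gc$inhibition %||% list()))
  qopt <- if (is.null(gc$qmax_opt)) NA_real_ else gc$qmax_opt
  microbial_group(
    id = gc$id,
    cardinal = cardinal_params(gc$T_min, gc$T_opt, gc$T_max,
                               if (is.na(qopt))
                                 qmax_opt_from_linear_rule(gc$T_opt)
                               else qopt),
    Y = gc$yield %||% 0.05, k_d = gc$k_d %||% 0.02,
    KS_coef = gc$KS_coef %||% 1, KS_SO4 = gc$KS_SO4,
    inhibition = inh, C_X_in = gc$C_X_in %||% 0.001,
    X_init = gc$X_init,
    is_sulfate_reducer = isTRUE(gc$is_sulfate_reducer))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_from_config <- function(cfg) {
  validate_config(cfg)
  defaults <- cfg$defaults %||% "paper-defaults"
  if (identical(defaults, "paper-defaults")) {
    base <- yaml::read_yaml(paper_defaults_path())
    base$defaults <- NULL
    cfg$defaults <- NULL
    cfg <- merge_config(base, cfg)
    validate_config(cfg)
  }
  groups <- lapply(cfg$groups, group_from_config)
  if (isTRUE(cfg$include_sulfate_reducer) &&
      !any(vapply(groups, `[[`, FALSE, "is_sulfate_reducer")))
    groups <- default_groups(include_sulfate_reducer = TRUE)
  h <- strip_prov(cfg$hydrolysis)
  f <- strip_prov(cfg$forcings %||% list(times = 0, temp_c = 20, ph = 7))
  mg <- strip_prov(cfg$management)
  mg$mode <- mg$mode %||% "threshold"
  scn <- scenario(
    groups = groups,
    hydrolysis = cardinal_params(h$T_min, h$T_opt, h$T_max, h$alpha_opt),
    ks_params = do.call(ks_temperature_params, strip_prov(cfg$ks_params)),
    influent = do.call(influent_composition, strip_prov(cfg$influent)),
    management = do.call(management_scheme, mg),
    transfer = do.call(transfer_params, strip_prov(cfg$transfer)),
    productivities = do.call(co2_productivities,
                             strip_prov(cfg$productivities %||% list())),
    forcings = forcing_series(f$times, f$temp_c, f$ph %||% 7,
                              f$slurry_mass),
    speciation = do.call(speciation_params, strip_prov(cfg$speciation)),
    solver = do.call(solver_settings, strip_prov(cfg$solver %||% list())),
    duration = cfg$duration %||% 365,
    n_warmup_cycles = cfg$n_warmup_cycles %||% 5,
    output_dt = cfg$output_dt %||% 1)
  scn$vs_conversion <- do.call(vs_conversion,
                               strip_prov(cfg$vs_conversion %||% list()))
  scn
}

#' Load a scenario from a YAML config file
#'
#' The config mirrors [scenario()]; any omitted block inherits from the
#' shipped `paper-defaults` parameter set (set `defaults: none` to disable
#' inheritance). Unknown keys are rejected with a message naming every
#' offending key; invariant violations name the key and its unit.
#'
#' @param path Path to a YAML scenario file.
#' @return A fully validated [scenario()] object.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  scenario_from_config(yaml::read_yaml(path))
}

scenario_to_config <- function(scn) {
  g2c <- function(g) {
    c(list(id = g$id, T_min = g$cardinal$T_min, T_opt = g$cardinal$T_opt,
           T_max = g$cardinal$T_max, qmax_opt = g$cardinal$rate_opt,
           yield = g$Y, k_d = g$k_d, KS_coef = g$KS_coef),
      if (!is.null(g$KS_SO4)) list(KS_SO4 = g$KS_SO4),
      list(C_X_in = g$C_X_in),
      if (!is.null(g$X_init)) list(X_init = g$X_init),
      list(is_sulfate_reducer = g$is_sulfate_reducer,
           inhibition = unclass(g$inhibition)))
  }
  f <- scn$forcings
  list(version = 1, defaults = "none",
       duration = scn$duration, output_dt = scn$output_dt,
       n_warmup_cycles = scn$n_warmup_cycles,
       groups = lapply(scn$groups, g2c),
       hydrolysis = list(T_min = scn$hydrolysis$T_min,
                         T_opt = scn$hydrolysis$T_opt,
                         T_max = scn$hydrolysis$T_max,
                         alpha_opt = scn$hydrolysis$rate_opt),
       ks_params = unclass(scn$ks_params),
       influent = unclass(scn$influent),
       management = Filter(Negate(is.null), unclass(scn$management)),
       transfer = unclass(scn$transfer),
       productivities = unclass(scn$productivities),
       speciation = unclass(scn$speciation),
       solver = Filter(Negate(is.null), unclass(scn$solver)),
       forcings = Filter(Negate(is.null),
                         list(times = f$times, temp_c = f$temp_c,
                              ph = f$ph, slurry_mass = f$slurry_mass)),
       vs_conversion = unclass(scn$vs_conversion %||% vs_conversion()))
}

#' Write a scenario to a YAML config file
#'
#' Emits the fully resolved parameter set (`defaults: none`), so
#' `load_scenario(write_scenario(x, p))` round-trips losslessly.
#'
#' @param scn A [scenario()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  yaml::write_yaml(scenario_to_config(scn), path, precision = 15)
  invisible(path)
}

#' Read a forcing table
#'
#' Delimited text with header columns `time_d`, `temp_c` and optionally
#' `ph` and `slurry_mass_kg`.
#'
#' @param path CSV path.
#' @return A [forcing_series()].
#' @export
read_forcing_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_d", "temp_c")
  if (!all(need %in% names(df)))
    stop("forcing table must have columns time_d, temp_c (missing: ",
         paste(setdiff(need, names(df)), collapse = ", "), ")")
  if (any(diff(df$time_d) <= 0))
    stop("time_d must be strictly increasing")
  forcing_series(df$time_d, df$temp_c,
                 ph = if ("ph" %in% names(df)) df$ph else 7,
                 slurry_mass = if ("slurry_mass_kg" %in% names(df))
                   df$slurry_mass_kg else NULL)
}

#' Write a trajectory to disk
#'
#' Writes the daily states and rates (`states.csv`), the removal-event log
#' (`events.csv`) and a machine-readable summary (`summary.json`) holding
#' the cumulative emissions, convergence status and the fully resolved
#' parameter set, so the run is reproducible from the output alone.
#'
#' @param traj A `slurry_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trajectory <- function(traj, out_dir) {
  stopifnot(inherits(traj, "slurry_trajectory"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(states = file.path(out_dir, "states.csv"),
             events = file.path(out_dir, "events.csv"),
             summary = file.path(out_dir, "summary.json"))
  utils::write.csv(traj$states, paths["states"], row.names = FALSE)
  utils::write.csv(traj$events, paths["events"], row.names = FALSE)
  s <- traj$summary
  s$final_state <- as.list(s$final_state)
  jsonlite::write_json(
    list(summary = s, convergence = traj$convergence,
         scenario = scenario_to_config(traj$scenario)),
    paths["summary"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
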