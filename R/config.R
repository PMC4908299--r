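#' Parse a physical quantity with an optional unit suffix
#'
#' Configuration values may carry unit suffixes, normalized to SI: voltages
#' `V`/`mV`, currents `A`/`nA`/`pA`/`fA`/`uA`, times `s`/`ms`/`us`,
#' capacitances `F`/`pF`/`fF`/`nF`, rates `/s` (`Hz`). Bare numbers pass
#' through unchanged.
#'
#' @param x A number, or a string like `"375 us"` or `"60 pA"`.
#' @return Numeric value in SI units.
#' @examples
#' parse_quantity("375 us")  # 3.75e-4
#' parse_quantity("60 pA")   # 6e-11
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(x)
  if (!is.character(x) || length(x) != 1L) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([a-zA-Z/]*)\\s*$", x))[[1L]]
  if (length(m) != 3L || m[2] == "") return(x)
  val <- as.numeric(m[2])
  if (is.na(val)) return(x)
  unit <- m[3]
  mult <- c(V = 1, mV = 1e-3, uV = 1e-6,
            A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, pA = 1e-12, fA = 1e-15,
            s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9,
            F = 1, uF = 1e-6, nF = 1e-9, pF = 1e-12, fF = 1e-15,
            Hz = 1, "/s" = 1)
  if (unit == "") return(val)
  if (!unit %in% names(mult)) stop("unknown unit suffix '", unit, "'")
  val * mult[[unit]]
}

.known_config_keys <- list(
  analog_sn = c("C_v", "I_a", "tau_n", "tau_q", "M_m", "delta_m", "M_n",
                "delta_n", "M_q", "delta_q", "S", "theta_v", "U_T", "kappa"),
  ulp_sn = c("C_v", "C_n", "I_av", "I_an", "I_0P", "M_v", "delta_v",
             "R_v20", "R_v21", "theta_v", "M_n", "delta_n", "R_n20",
             "R_n21", "theta_n", "theta_r", "U_T", "kappa"),
  dssn = c("phi", "tau", "I_0", "a_fn", "b_fn", "c_fn", "a_fp", "b_fp",
           "c_fp", "a_gn", "b_gn", "c_gn", "a_gp", "b_gp", "c_gp", "r_g",
           "fixed_point"),
  fixed_point = c("total_bits", "frac_bits", "rounding", "overflow"),
  synapse = c("alpha", "beta"),
  stdp = c("A_plus", "A_minus", "tau_plus", "tau_minus"),
  experiment = c("preset", "mode", "dt", "T", "seed", "I_stim", "stimulus",
                 "I_ext", "pulse_amp", "pulse_steps", "c_scale", "theta_M",
                 "theta_other", "T_total", "metric_dt", "error_levels",
                 "trials_per_level", "n_patterns", "learning", "out",
                 "v_range", "param", "range", "resolution", "target",
                 "bounds", "n_iter", "fixed_point"))

#' Load and validate a run configuration
#'
#' A run configuration is a YAML file with blocks `analog_sn`, `ulp_sn`,
#' `dssn` (with optional nested `fixed_point`), `synapse`, `stdp` and
#' `experiment`. Keys are validated against the schema (unknown keys are an
#' error naming the offending path) and unit-suffixed strings are
#' normalized to SI.
#'
#' @param path Path to the YAML file.
#' @return A named list of class `run_config` with all quantities in SI.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  unknown_block <- setdiff(names(raw), names(.known_config_keys))
  if (length(unknown_block))
    stop("unknown config block: ", paste(unknown_block, collapse = ", "))
  parse_block <- function(block, name) {
    unknown <- setdiff(names(block), .known_config_keys[[name]])
    if (length(unknown))
      stop("unknown key ", name, ".", unknown[1L])
    lapply(stats::setNames(names(block), names(block)), function(k) {
      v <- block[[k]]
      if (is.list(v) && k %in% names(.known_config_keys))
        parse_block(v, k)
      else if (is.list(v)) lapply(v, parse_quantity)
      else parse_quantity(v)
    })
  }
  out <- lapply(stats::setNames(names(raw), names(raw)), function(b)
    parse_block(raw[[b]], b))
  class(out) <- c("run_config", "list")
  out
}

#' Build a model from a loaded configuration
#'
#' @param cfg A [load_config()] result containing one model block (or an
#'   `experiment.preset` reference).
#' @return A `qsn_model`.
#' @export
model_from_config <- function(cfg) {
  if (!is.null(cfg$experiment$preset)) return(qsn_preset(cfg$experiment$preset))
  if (!is.null(cfg$analog_sn)) {
    p <- cfg$analog_sn
    return(analog_sn(p$C_v, p$I_a, p$tau_n, p$tau_q,
                     sigmoid_spec(p$M_m, p$delta_m),
                     sigmoid_spec(p$M_n, p$delta_n),
                     sigmoid_spec(p$M_q, p$delta_q),
                     tanh_spec(p$S, p$theta_v),
                     thermal_constants(p$U_T %||% 0.026,
                                       p$kappa %||% 0.7)))
  }
  if (!is.null(cfg$ulp_sn)) {
    p <- cfg$ulp_sn
    return(ulp_sn(p$C_v %||% 1.5e-12, p$C_n %||% 2.0e-12, p$I_av, p$I_an,
                  p$I_0P,
                  ulp_curve_spec(p$M_v, p$delta_v, p$R_v20 %||% 1,
                                 p$R_v21 %||% 1, p$theta_v),
                  ulp_curve_spec(p$M_n, p$delta_n, p$R_n20 %||% 1,
                                 p$R_n21 %||% 1, p$theta_n),
                  p$theta_r,
                  thermal_constants(p$U_T %||% 0.026, p$kappa %||% 0.7)))
  }
  if (!is.null(cfg$dssn)) {
    p <- cfg$dssn
    p$fixed_point <- NULL
    return(do.call(dssn, p))
  }
  stop("config contains no model block and no experiment.preset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Every command-line run emits a manifest capturing the fully resolved
#' configuration, the seed and the package version, sufficient to
#' regenerate the outputs.
#'
#' @param path Output path (JSON).
#' @param config Resolved configuration list.
#' @param seed The run seed.
#' @param command The command name.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NULL, command = "") {
  jsonlite::write_json(
    list(package = "qsn",
         version = as.character(utils::packageVersion("qsn")),
         command = command, seed = seed, config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
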