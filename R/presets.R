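#' Shipped mode presets
#'
#' The mode parameter values of the silicon neuron models are not
#' published; the shipped presets were derived with the package's own
#' [tune_mode()] search plus verification by the classification and sweep
#' operations, and are frozen as plain-text fixture files (one YAML file
#' per preset under `extdata/presets`, carrying the provenance, the seed
#' and the characterization numbers). Available presets:
#' \describe{
#'   \item{dssn_class1}{digital neuron, Class I excitability (three
#'     equilibria, saddle-node-on-invariant-circle onset);}
#'   \item{dssn_class2}{digital neuron, Class II excitability (single
#'     equilibrium, subcritical-Hopf onset, graded responses);}
#'   \item{analog_square_wave}{three-variable analog neuron in the
#'     autonomous square-wave-bursting mode;}
#'   \item{ulp_class1, ulp_class2}{ultralow-power two-variable neuron in
#'     the Class I / Class II modes.}
#' }
#'
#' @param name Preset name.
#' @return A `qsn_model` with characterization attributes attached
#'   (`spike_threshold`, and where relevant `sustained_I`, `c_scale`,
#'   `I_probe`).
#' @examples
#' m <- qsn_preset("dssn_class2")
#' find_equilibria(m)
#' @export
qsn_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "qsn")
  if (path == "") stop("unknown preset '", name, "'")
  spec <- yaml::read_yaml(path)
  p <- lapply(spec$params, parse_quantity)
  model <- switch(spec$family,
    dssn = do.call(dssn, p),
    analog_sn = analog_sn(
      C_v = p$C_v, I_a = p$I_a, tau_n = p$tau_n, tau_q = p$tau_q,
      fm = sigmoid_spec(p$M_m, p$delta_m),
      fn = sigmoid_spec(p$M_n, p$delta_n),
      fq = sigmoid_spec(p$M_q, p$delta_q),
      g = tanh_spec(p$S, p$theta_v),
      consts = thermal_constants(p$U_T, p$kappa)),
    ulp_sn = ulp_sn(
      C_v = p$C_v, C_n = p$C_n, I_av = p$I_av, I_an = p$I_an,
      I_0P = p$I_0P,
      curve_v = ulp_curve_spec(p$M_v, p$delta_v, p$R_v20, p$R_v21,
                               p$theta_v),
      curve_n = ulp_curve_spec(p$M_n, p$delta_n, p$R_n20, p$R_n21,
                               p$theta_n),
      theta_r = p$theta_r,
      consts = thermal_constants(p$U_T, p$kappa)),
    stop("unknown preset family '", spec$family, "'"))
  for (a in names(spec$attributes))
    attr(model, a) <- parse_quantity(spec$attributes[[a]])
  attr(model, "preset") <- name
  model
}

#' List the shipped presets
#' @return Character vector of preset names.
#' @export
qsn_presets <- function() {
  dir <- system.file("extdata", "presets", package = "qsn")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}
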