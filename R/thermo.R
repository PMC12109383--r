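# Van't Hoff regression, Gibbs energy and binding-force classification.

GAS_CONSTANT <- 8.314  # J mol^-1 K^-1

#' Van't Hoff fit of binding constants across temperatures
#'
#' Ordinary least squares of ln Ka on 1/T per the Van't Hoff relation
#' ln Ka = -dH/(R T) + dS/R: the enthalpy change is -R times the slope and
#' the entropy change R times the intercept. With exactly two temperatures
#' the line is determined and standard errors are reported as `NA`.
#' Internal units are J/mol and J/(mol K) throughout; convert to kJ only
#' when printing.
#'
#' @param ka_by_temperature Two-column data frame (or matrix) with
#'   temperature in K and Ka in L/mol, or a named numeric vector of Ka
#'   values whose names are temperatures.
#' @return A list of class `"vant_hoff_fit"`: `dh` (J/mol), `ds`
#'   (J/(mol K)), `r_squared`, `se_dh`, `se_ds`, `gas_constant`, `n_temps`,
#'   `temperatures`, `ka`.
#' @examples
#' vant_hoff(data.frame(temperature_K = c(298, 304, 310),
#'                      ka_per_M = c(7.16e4, 5.56e4, 5.45e4)))
#' @export
vant_hoff <- function(ka_by_temperature) {
  if (is.numeric(ka_by_temperature) && !is.null(names(ka_by_temperature))) {
    temps <- as.numeric(names(ka_by_temperature))
    ka <- unname(ka_by_temperature)
  } else {
    m <- as.data.frame(ka_by_temperature)
    stopifnot(ncol(m) >= 2L)
    temps <- as.numeric(m[[1L]])
    ka <- as.numeric(m[[2L]])
  }
  if (length(temps) < 2L) {
    stop_quenchlab("Van't Hoff fit needs at least 2 temperatures", "quenchlab_fit_error")
  }
  if (anyDuplicated(temps)) {
    stop_quenchlab("duplicate temperatures in Van't Hoff input", "quenchlab_fit_error")
  }
  if (any(ka <= 0)) {
    stop_quenchlab("all Ka values must be positive", "quenchlab_domain_error")
  }
  if (any(temps <= 0)) {
    stop_quenchlab("temperatures must be positive (K)", "quenchlab_domain_error")
  }
  fit <- ols(1 / temps, log(ka))
  two_pt <- length(temps) == 2L
  structure(
    list(
      dh = -GAS_CONSTANT * fit$slope,
      ds = GAS_CONSTANT * fit$intercept,
      r_squared = if (two_pt) 1 else fit$r_squared,
      se_dh = if (two_pt) NA_real_ else GAS_CONSTANT * fit$se_slope,
      se_ds = if (two_pt) NA_real_ else GAS_CONSTANT * fit$se_intercept,
      gas_constant = GAS_CONSTANT,
      n_temps = length(temps),
      temperatures = temps,
      ka = ka
    ),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %s kJ/mol, dS = %s J/(mol K), R^2 = %.4f (%d temperatures)\n",
              fmt_num(x$dh / 1000), fmt_num(x$ds), x$r_squared, x$n_temps))
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' dG = dH - T dS; a negative dG marks spontaneous binding.
#'
#' @param dh Enthalpy change, J/mol.
#' @param ds Entropy change, J/(mol K).
#' @param temperature Temperature(s), K.
#' @return A tibble of class `"gibbs_result"` with columns `temperature`,
#'   `dg` (J/mol) and `spontaneous`.
#' @examples
#' gibbs(25400, 173.46, c(298, 304, 310))
#' @export
gibbs <- function(dh, ds, temperature) {
  stopifnot(is_number(dh), is_number(ds), is.numeric(temperature))
  if (any(temperature <= 0)) {
    stop_quenchlab("temperature must be positive (K)", "quenchlab_domain_error")
  }
  dg <- dh - temperature * ds
  out <- tibble::tibble(temperature = temperature, dg = dg, spontaneous = dg < 0)
  class(out) <- c("gibbs_result", class(out))
  out
}

#' Classify the dominant binding forces from thermodynamic signs
#'
#' Sign-quadrant interpretation of (dH, dS): both positive, hydrophobic
#' interactions dominate; dH negative with dS positive, electrostatic
#' forces; dH positive with dS negative, electrostatic plus hydrophobic;
#' both negative, van der Waals forces and hydrogen bonding. Values inside
#' the zero bands are treated as sign 0 and yield `"indeterminate"`.
#'
#' @param dh Enthalpy change, J/mol.
#' @param ds Entropy change, J/(mol K).
#' @param epsilon_dh Zero band for dH, J/mol.
#' @param epsilon_ds Zero band for dS, J/(mol K).
#' @return A list of class `"force_call"`: `label`, `dh_sign`, `ds_sign`,
#'   `epsilon_dh`, `epsilon_ds`.
#' @examples
#' classify_forces(25400, 173.46)  # hydrophobic
#' @export
classify_forces <- function(dh, ds, epsilon_dh = 100, epsilon_ds = 1) {
  stopifnot(is_number(dh), is_number(ds), epsilon_dh >= 0, epsilon_ds >= 0)
  sgn <- function(x, eps) if (abs(x) <= eps) 0L else if (x > 0) 1L else -1L
  dh_sign <- sgn(dh, epsilon_dh)
  ds_sign <- sgn(ds, epsilon_ds)
  label <- if (dh_sign == 0L || ds_sign == 0L) {
    "indeterminate"
  } else if (dh_sign > 0L && ds_sign > 0L) {
    "hydrophobic"
  } else if (dh_sign < 0L && ds_sign > 0L) {
    "electrostatic"
  } else if (dh_sign > 0L && ds_sign < 0L) {
    "electrostatic+hydrophobic"
  } else {
    "vdw+hbond"
  }
  structure(
    list(label = label, dh_sign = dh_sign, ds_sign = ds_sign,
         epsilon_dh = epsilon_dh, epsilon_ds = epsilon_ds),
    class = "force_call"
  )
}

#' @export
print.force_call <- function(x, ...) {
  cat(sprintf("<force_call> %s (sign dH = %+d, sign dS = %+d)\n",
              x$label, x$dh_sign, x$ds_sign))
  invisible(x)
}
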