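#' Two-state duplex melting model
#'
#' Unfolded (single-strand) fraction of a bimolecular, non-self-complementary
#' duplex under the concentration convention used by the van 't Hoff fitter:
#' the melting midpoint satisfies `1/Tm = (R/dH) * ln(Ct/c_div) + dS/dH`
#' exactly, with `c_div = 2` by default.  The association constant is
#' `K(T) = exp(dS/R - dH/(R T))` and the unfolded fraction is the logistic
#' `1 / (1 + K(T) Ct / c_div)`.
#'
#' @param temperature_K Temperatures in kelvin.
#' @param dH Association enthalpy, kcal/mol (negative).
#' @param dS Association entropy, kcal/mol/K (negative).
#' @param ct Total strand concentration, mol/L.
#' @param conc_divisor Concentration convention divisor; 2 matches the
#'   `ln(Ct/2)` fit, 4 the textbook non-self-complementary form.
#' @return Unfolded fraction in (0, 1), same length as `temperature_K`.
#' @export
two_state_unfolded <- function(temperature_K, dH, dS, ct, conc_divisor = 2) {
  R <- phys_constants()$R_kcal
  u <- dS / R - dH / (R * temperature_K) + log(ct / conc_divisor)
  stats::plogis(-u)
}

#' Closed-form melting temperature of the two-state model
#'
#' Solves `1/Tm = (R/dH) * ln(Ct/c_div) + dS/dH` for Tm.
#'
#' @inheritParams two_state_unfolded
#' @return Melting temperature in kelvin.
#' @examples
#' tm_two_state(-100, -0.270, 2.5e-6) # 336.7 K
#' @export
tm_two_state <- function(dH, dS, ct, conc_divisor = 2) {
  R <- phys_constants()$R_kcal
  1 / ((R / dH) * log(ct / conc_divisor) + dS / dH)
}

#' Simulate a UV melting curve
#'
#' Generates a temperature/absorbance series from the two-state duplex model
#' with linear low- and high-temperature baselines and optional Gaussian
#' absorbance noise:
#' `A(T) = b_low(T) + theta(T) * (b_high(T) - b_low(T)) + noise`.
#'
#' @param dH,dS Association enthalpy (kcal/mol) and entropy (kcal/mol/K),
#'   both negative for duplex formation.
#' @param ct Total strand concentration in mol/L.
#' @param t_grid Strictly increasing temperatures in kelvin.
#' @param baseline_low,baseline_high Length-2 numeric `(intercept, slope)` of
#'   the folded and unfolded absorbance baselines (absorbance units; slope
#'   per kelvin).
#' @param noise_sd Standard deviation of additive Gaussian absorbance noise.
#' @param conc_divisor See [two_state_unfolded()].
#' @param condition,sequence_id Labels carried along for bookkeeping.
#' @param seed Integer seed for reproducible noise, or NULL.
#' @return A `melting_curve` tibble with columns `temperature_K`,
#'   `absorbance`, `ct_M`, `condition`, `sequence_id`.
#' @examples
#' crv <- simulate_melting_curve(-100, -0.270, 2.5e-6,
#'                               t_grid = seq(300, 370, 0.25))
#' find_tm(crv)
#' @export
simulate_melting_curve <- function(dH, dS, ct,
                                   t_grid = seq(293.15, 373.15, by = 0.5),
                                   baseline_low = c(0, 0),
                                   baseline_high = c(1, 0),
                                   noise_sd = 0,
                                   conc_divisor = 2,
                                   condition = "synthetic",
                                   sequence_id = "synthetic",
                                   seed = NULL) {
  abort_if(dH >= 0, "`dH` must be negative (association direction)")
  abort_if(dS >= 0, "`dS` must be negative (association direction)")
  abort_if(ct <= 0, "`ct` must be a positive strand concentration in mol/L")
  abort_if(length(t_grid) < 7L || any(diff(t_grid) <= 0),
           "`t_grid` must be strictly increasing with at least 7 points")
  abort_if(noise_sd < 0, "`noise_sd` must be non-negative")

  theta <- two_state_unfolded(t_grid, dH, dS, ct, conc_divisor)
  b_lo <- baseline_low[1L] + baseline_low[2L] * t_grid
  b_hi <- baseline_high[1L] + baseline_high[2L] * t_grid
  noise <- with_seed_(seed, stats::rnorm(length(t_grid), 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, length(t_grid))

  new_melting_curve(tibble::tibble(
    temperature_K = as.numeric(t_grid),
    absorbance = b_lo + theta * (b_hi - b_lo) + noise,
    ct_M = ct,
    condition = condition,
    sequence_id = sequence_id
  ))
}

new_melting_curve <- function(x) {
  class(x) <- c("melting_curve", class(tibble::tibble()))
  x
}

#' Read a melting curve from CSV
#'
#' Expects columns `temperature` and `absorbance`; temperatures may be given
#' in degrees Celsius (the default for instrument exports) or kelvin.
#'
#' @param path CSV file path.
#' @param unit Temperature unit in the file, `"C"` or `"K"`.
#' @param ct Total strand concentration (mol/L) for the curve.
#' @param condition,sequence_id Labels.
#' @return A `melting_curve` tibble (temperatures in kelvin).
#' @export
read_melting_curve <- function(path, unit = c("C", "K"), ct = NA_real_,
                               condition = "unknown",
                               sequence_id = "unknown") {
  unit <- match.arg(unit)
  x <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(!all(c("temperature", "absorbance") %in% names(x)),
           "melting CSV must have columns `temperature` and `absorbance`")
  tk <- if (unit == "C") celsius_to_kelvin(x$temperature) else x$temperature
  new_melting_curve(tibble::tibble(
    temperature_K = tk,
    absorbance = x$absorbance,
    ct_M = ct,
    condition = condition,
    sequence_id = sequence_id
  ))
}

#' Write a melting curve to CSV
#'
#' @param curve A `melting_curve` tibble.
#' @param path Output CSV path (columns `temperature_K`, `absorbance`).
#' @return `path`, invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  readr::write_csv(curve[, c("temperature_K", "absorbance")], path)
  invisible(path)
}
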