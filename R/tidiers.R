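#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a van 't Hoff fit
#'
#' @param x A `vant_hoff_fit`.
#' @param ... Unused.
#' @return Tibble with one row per thermodynamic parameter (`term`,
#'   `estimate`, `unit`).
#' @export
tidy.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH", "dS", paste0("dG", x$t_ref)),
    estimate = c(x$dH_kcal, x$dS_kcal, x$dG_ref_kcal),
    unit = c("kcal/mol", "kcal/mol/K", "kcal/mol")
  )
}

#' Glance at a van 't Hoff fit
#'
#' @inheritParams tidy.vant_hoff_fit
#' @return One-row tibble with the parameters, fit quality and direction.
#' @export
glance.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(
    dH_kcal = x$dH_kcal, dS_kcal = x$dS_kcal, dG_ref_kcal = x$dG_ref_kcal,
    t_ref = x$t_ref, r2 = x$r2, n = nrow(x$tm_by_ct),
    direction = x$direction
  )
}

#' Tidy a free-energy estimate
#'
#' @param x A `fep_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the estimate in both energy units.
#' @export
tidy.fep_estimate <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_, method = x$method,
    dG_kJ = x$dG_kJ, dG_kT = x$dG_kT, stderr_kJ = x$stderr_kJ,
    n_F = x$n_F, n_R = x$n_R, temperature = x$temperature
  )
}

#' @rdname tidy.fep_estimate
#' @export
glance.fep_estimate <- function(x, ...) tidy.fep_estimate(x)

#' Tidy an essential-dynamics result
#'
#' @param x An `ed_result`.
#' @param ... Unused.
#' @return Tibble `index, eigenvalue`.
#' @export
tidy.ed_result <- function(x, ...) {
  tibble::tibble(index = seq_along(x$values), eigenvalue = x$values)
}

#' Glance at an essential-dynamics result
#'
#' @inheritParams tidy.ed_result
#' @return One-row tibble with `sum_first_k`, `k`, `trace`, `n_frames`.
#' @export
glance.ed_result <- function(x, ...) {
  tibble::tibble(sum_first_k = x$sum_first_k, k = x$k, trace = x$trace,
                 n_frames = x$n_frames)
}

#' Tidy a thermodynamic-cycle result
#'
#' @param x A `cycle_result`.
#' @param ... Unused.
#' @return The per-context tibble of `ddG` values.
#' @export
tidy.cycle_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Glance at a thermodynamic-cycle result
#'
#' @inheritParams tidy.cycle_result
#' @return The per-salt significance-test tibble.
#' @export
glance.cycle_result <- function(x, ...) {
  attr(x, "tests")
}

#' Tidy an MSD result
#'
#' @param x An `msd_result`.
#' @param ... Unused.
#' @return The MSD curve tibble `tau_ns, msd`.
#' @export
tidy.msd_result <- function(x, ...) x$msd

#' Glance at an MSD result
#'
#' @inheritParams tidy.msd_result
#' @return One-row tibble with `D`, fit diagnostics and the flag.
#' @export
glance.msd_result <- function(x, ...) {
  tibble::tibble(D = x$D, slope = x$slope, intercept = x$intercept,
                 r2 = x$r2, nonlinear_flag = x$nonlinear_flag,
                 t0 = x$fit_window[1L], t1 = x$fit_window[2L])
}
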