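#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a melting curve
#'
#' Absorbance versus temperature with an optional Tm marker.
#'
#' @param object A `melting_curve`.
#' @param tm Optional Tm (kelvin) to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.melting_curve <- function(object, tm = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$temperature_K,
                                    y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (K)", y = "Absorbance (a.u.)")
  if (!is.null(tm)) {
    p <- p + ggplot2::geom_vline(xintercept = tm, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' Plot a van 't Hoff fit
#'
#' 1/Tm against ln(Ct/divisor) with the least-squares line.
#'
#' @param object A `vant_hoff_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vant_hoff_fit <- function(object, ...) {
  d <- tibble::tibble(
    x = log(object$tm_by_ct$ct_M / object$conc_divisor),
    y = 1 / object$tm_by_ct$tm_K
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = sprintf("ln(Ct/%g)", object$conc_divisor),
                  y = "1/Tm (1/K)")
}

#' Plot a radial-angular density map
#'
#' Tile map of molarity (or bulk ratio) over the radius/azimuth grid; use
#' `polar = TRUE` for the groove-sector view.
#'
#' @param object A `density_map`.
#' @param fill `"molarity"` or `"ratio"` (requires [bulk_ratio()]).
#' @param polar Draw in polar coordinates?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, fill = "molarity", polar = FALSE,
                                 ...) {
  abort_if(!fill %in% names(object), paste0("no column `", fill, "` in map"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$a_mid, y = .data$r_mid,
                                    fill = .data[[fill]])) +
    ggplot2::geom_tile(width = object$a_hi - object$a_lo,
                       height = object$r_hi - object$r_lo) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Azimuth (deg)", y = "R (Å)", fill = fill)
  if (polar) p <- p + ggplot2::coord_polar(theta = "x")
  p
}

#' Plot forward and mirrored-reverse work densities
#'
#' Kernel density estimates of `P_F(W)` and `P_R(-W)`; their crossing is the
#' Crooks free-energy estimate.
#'
#' @param object A `work_set`.
#' @param estimate Optional `fep_estimate` whose dG is marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.work_set <- function(object, estimate = NULL, ...) {
  s <- work_split(object)
  d <- dplyr::bind_rows(
    tibble::tibble(work = s$wf, which = "forward W"),
    tibble::tibble(work = -s$wr, which = "reverse -W")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$work,
                                       colour = .data$which)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Work (kJ/mol)", y = "Density", colour = NULL)
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = estimate$dG_kJ, linetype = 2)
  }
  p
}

#' Scree plot of an essential-dynamics result
#'
#' @param object An `ed_result`.
#' @param n_show Number of leading eigenvalues to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ed_result <- function(object, n_show = 20L, ...) {
  d <- tidy.ed_result(object)
  d <- d[seq_len(min(n_show, nrow(d))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mode", y = "Eigenvalue (Å²)")
}

#' Plot an MSD curve with its linear fit window
#'
#' @param object An `msd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_result <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(x = .data$tau_ns, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$fit_window, linetype = 3) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue", linetype = 2) +
    ggplot2::labs(x = "Lag time (ns)", y = "MSD (Å²)")
}

#' Plot pure force constants per step
#'
#' Diagonal ("pure") stiffness constants along the sequence, one panel per
#' parameter.
#'
#' @param object A `stiffness_result`.
#' @param parameters Which diagonal constants to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stiffness_result <- function(object,
                                      parameters = c("shift", "slide", "roll"),
                                      ...) {
  d <- pure_force_constants(object)
  d <- d[d$parameter %in% parameters, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Step", y = "Force constant (kJ/mol per unit²)")
}

#' Plot cycle results per mutation context
#'
#' @param object A `cycle_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cycle_result <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(unclass(object)),
                           dplyr::starts_with("ddG"),
                           names_to = "leg", values_to = "ddG")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$ddG,
                                  fill = .data$leg)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~salt) +
    ggplot2::labs(x = NULL, y = "ΔΔG (kJ/mol)", fill = NULL)
}
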