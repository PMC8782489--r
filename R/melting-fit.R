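#' Savitzky-Golay smoothing of a melting curve
#'
#' Local least-squares polynomial smoothing.  Each point is replaced by the
#' value at that point of a polynomial of degree `order` fitted to a window
#' of `window` neighbours; near the series ends the window is shrunk rather
#' than padded, so the temperature grid is unchanged.
#'
#' @param curve A `melting_curve` tibble (or any tibble with `temperature_K`
#'   and `absorbance` columns).
#' @param window Odd window length, `window > order` and `window <= n`.
#' @param order Polynomial order, at least 1.
#' @return The curve with `absorbance` replaced by its smoothed values.
#' @export
smooth_curve <- function(curve, window = 11L, order = 3L) {
  n <- nrow(curve)
  abort_if(window %% 2L == 0L, "`window` must be odd")
  abort_if(window > n, "`window` must not exceed the number of points")
  abort_if(order < 1L || order >= window, "need `window` > `order` >= 1")
  curve$absorbance <- sg_smooth(curve$temperature_K, curve$absorbance,
                                as.integer(window), as.integer(order))
  curve
}

sg_smooth <- function(x, y, window, order, deriv = FALSE) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    xi <- x[lo:hi] - x[i]
    p <- min(order, length(xi) - 1L)
    X <- outer(xi, 0:p, `^`)
    cf <- stats::.lm.fit(X, y[lo:hi])$coefficients
    out[i] <- if (deriv) {
      if (p >= 1L) cf[2L] else 0
    } else {
      cf[1L]
    }
  }
  out
}

#' Melting temperature from the smoothed first derivative
#'
#' Tm is located at the maximum of dA/dT of the Savitzky-Golay-smoothed
#' curve, refined by fitting a quadratic through the grid maximum and its two
#' neighbours.  A maximum at the grid boundary means the transition was not
#' captured and is an error.
#'
#' @inheritParams smooth_curve
#' @return Melting temperature in kelvin.
#' @examples
#' crv <- simulate_melting_curve(-100, -0.270, 2.5e-6,
#'                               t_grid = seq(300, 370, 0.25))
#' find_tm(crv) # ~336.7 K
#' @export
find_tm <- function(curve, window = 11L, order = 3L) {
  abort_if(nrow(curve) < max(7L, window),
           "curve too short for the requested smoothing window")
  sm <- smooth_curve(curve, window, order)
  tt <- sm$temperature_K
  aa <- sm$absorbance
  n <- length(tt)
  # central-difference derivative on interior points (the one-sided endpoint
  # estimates have double the noise and are not candidates for the peak)
  d <- rep(-Inf, n)
  d[2:(n - 1L)] <- (aa[3:n] - aa[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)])
  j <- which.max(d)
  abort_if(j <= 2L || j >= n - 1L,
           "transition not captured: derivative maximum at the grid boundary")
  quad_peak(tt[(j - 1L):(j + 1L)], d[(j - 1L):(j + 1L)])
}

# Vertex abscissa of the parabola through three (x, y) points.
quad_peak <- function(x3, y3) {
  X <- cbind(1, x3, x3^2)
  cf <- unname(solve(X, y3))
  if (abs(cf[3L]) < 1e-300) return(unname(x3[2L]))
  v <- -cf[2L] / (2 * cf[3L])
  unname(if (v < x3[1L] || v > x3[3L]) x3[2L] else v)
}

#' Van 't Hoff fit of Tm versus strand concentration
#'
#' Ordinary least squares of `1/Tm` on `ln(Ct/2)` (divisor configurable).
#' With slope `s` and intercept `b`, the association-direction parameters are
#' `dH = R/s` (kcal/mol), `dS = b * dH` (kcal/mol/K) and
#' `dG(T_ref) = dH - T_ref * dS`.
#'
#' @param tm_by_ct Tibble (or data frame) with columns `ct_M` (mol/L) and
#'   `tm_K` (kelvin); at least 3 distinct concentrations.
#' @param t_ref Reference temperature for the free energy, kelvin.
#' @param conc_divisor Concentration convention divisor (2 by default).
#' @return An object of class `vant_hoff_fit` with elements `dH_kcal`,
#'   `dS_kcal`, `dG_ref_kcal`, `t_ref`, `r2`, `direction` ("association"),
#'   `conc_divisor`, `tm_by_ct` and the underlying `lm` fit.  Use [tidy()]
#'   and [glance()] to extract results.
#' @export
fit_vant_hoff <- function(tm_by_ct, t_ref = 300, conc_divisor = 2) {
  tm_by_ct <- tibble::as_tibble(tm_by_ct)
  abort_if(!all(c("ct_M", "tm_K") %in% names(tm_by_ct)),
           "`tm_by_ct` needs columns `ct_M` and `tm_K`")
  abort_if(length(unique(tm_by_ct$ct_M)) < 3L,
           "need at least 3 distinct strand concentrations")
  x <- log(tm_by_ct$ct_M / conc_divisor)
  abort_if(stats::var(x) == 0, "zero variance in ln(Ct) predictor")
  y <- 1 / tm_by_ct$tm_K
  fit <- stats::lm(y ~ x)
  s <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  R <- phys_constants()$R_kcal
  dH <- R / s
  dS <- b * dH
  structure(
    list(
      dH_kcal = dH,
      dS_kcal = dS,
      dG_ref_kcal = dH - t_ref * dS,
      t_ref = t_ref,
      # noiseless round trips fit perfectly; summary.lm's warning about it
      # is expected there and not informative
      r2 = suppressWarnings(summary(fit)$r.squared),
      direction = "association",
      conc_divisor = conc_divisor,
      tm_by_ct = tm_by_ct,
      fit = fit
    ),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("Van 't Hoff fit (", x$direction, " direction, ln(Ct/",
      x$conc_divisor, "))\n", sep = "")
  cat(sprintf("  dH = %.3f kcal/mol\n  dS = %.6f kcal/mol/K\n", x$dH_kcal, x$dS_kcal))
  cat(sprintf("  dG(%g K) = %.3f kcal/mol\n  r2 = %.5f  (n = %d)\n",
              x$t_ref, x$dG_ref_kcal, x$r2, nrow(x$tm_by_ct)))
  invisible(x)
}

#' Flip a van 't Hoff result between association and melting directions
#'
#' The melting reaction is the reverse of association, so all three
#' thermodynamic parameters change sign.
#'
#' @param params A `vant_hoff_fit`.
#' @return The same object with signs and direction flag flipped.
#' @export
flip_direction <- function(params) {
  abort_if(!inherits(params, "vant_hoff_fit"), "expected a `vant_hoff_fit`")
  params$dH_kcal <- -params$dH_kcal
  params$dS_kcal <- -params$dS_kcal
  params$dG_ref_kcal <- -params$dG_ref_kcal
  params$direction <- if (params$direction == "association") "melting" else "association"
  params
}

#' Tm differences between matched conditions
#'
#' Replicate Tm values within a condition are averaged (the spread is
#' reported); the difference is `a - b` per condition.
#'
#' @param a,b Tibbles with columns `condition` and `tm_K`.
#' @return Tibble with per-condition means, replicate spreads (sd) and
#'   `delta_tm_K`.
#' @export
delta_tm <- function(a, b) {
  summarise_tm <- function(x, who) {
    abort_if(!all(c("condition", "tm_K") %in% names(x)),
             paste0("`", who, "` needs columns `condition` and `tm_K`"))
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$condition),
                     tm_mean = mean(.data$tm_K),
                     tm_sd = stats::sd(.data$tm_K),
                     n = dplyr::n(), .groups = "drop")
  }
  sa <- summarise_tm(a, "a")
  sb <- summarise_tm(b, "b")
  abort_if(!setequal(sa$condition, sb$condition),
           "condition labels of `a` and `b` do not match")
  out <- dplyr::inner_join(sa, sb, by = "condition", suffix = c("_a", "_b"))
  dplyr::mutate(out, delta_tm_K = .data$tm_mean_a - .data$tm_mean_b)
}

#' Tm relative to a reference buffer
#'
#' Differences of each condition's Tm against a named reference condition
#' (e.g. the NaP control buffer).
#'
#' @param tm_tbl Tibble with columns `condition` and `tm_K` (replicates
#'   allowed; they are averaged).
#' @param reference Name of the reference condition.
#' @return Tibble with `condition`, `tm_mean`, `delta_tm_K` (condition minus
#'   reference); the reference row has `delta_tm_K = 0`.
#' @export
delta_tm_vs_reference <- function(tm_tbl, reference = "NaP") {
  s <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tm_tbl), .data$condition),
                        tm_mean = mean(.data$tm_K), .groups = "drop")
  abort_if(!reference %in% s$condition,
           paste0("reference condition '", reference, "' not present"))
  ref <- s$tm_mean[s$condition == reference]
  dplyr::mutate(s, delta_tm_K = .data$tm_mean - ref)
}

#' Differences of melting thermodynamics between conditions
#'
#' Component-wise differences of two van 't Hoff results, reported in the
#' melting-direction sign convention (duplex -> single strands).  Both inputs
#' must carry the same direction flag.
#'
#' @param cond,ref `vant_hoff_fit` objects for the condition of interest and
#'   the reference buffer.
#' @return One-row tibble with `ddH_kcal`, `ddS_kcal`, `ddG_ref_kcal` and
#'   `direction = "melting"`.
#' @export
thermo_deltas <- function(cond, ref) {
  abort_if(!inherits(cond, "vant_hoff_fit") || !inherits(ref, "vant_hoff_fit"),
           "both inputs must be `vant_hoff_fit` objects")
  abort_if(cond$direction != ref$direction,
           "direction flags differ; flip one input with flip_direction()")
  abort_if(cond$t_ref != ref$t_ref, "reference temperatures differ")
  sgn <- if (cond$direction == "association") -1 else 1
  tibble::tibble(
    ddH_kcal = sgn * (cond$dH_kcal - ref$dH_kcal),
    ddS_kcal = sgn * (cond$dS_kcal - ref$dS_kcal),
    ddG_ref_kcal = sgn * (cond$dG_ref_kcal - ref$dG_ref_kcal),
    t_ref = cond$t_ref,
    direction = "melting"
  )
}

#' GC content of a DNA sequence
#'
#' @param sequence DNA string over A, C, G, T.
#' @return Fraction of G+C bases in `[0, 1]`.
#' @examples
#' gc_content("TATGTATATTTTGTAATTAA") # 0.10
#' @export
gc_content <- function(sequence) {
  bases <- check_dna_sequence(sequence)
  mean(bases %in% c("G", "C"))
}
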