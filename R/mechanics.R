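#' Kullback-Leibler divergence between two sample sets
#'
#' Histogram estimate of `D_KL(a || b)` in nats on shared bins spanning the
#' pooled sample range; a pseudocount is added to every bin before
#' normalization so disjoint supports stay finite.
#'
#' @param a,b Numeric samples (at least 100 each for a stable histogram).
#' @param bins Number of shared bins.
#' @param pseudocount Count added to every bin of both histograms.
#' @return Non-negative divergence in nats.
#' @examples
#' set.seed(1)
#' kl_divergence(rnorm(1e4), rnorm(1e4, 1)) # ~0.5
#' @export
kl_divergence <- function(a, b, bins = 50L, pseudocount = 1e-6) {
  abort_if(length(a) < 100L || length(b) < 100L,
           "need at least 100 samples in each set")
  abort_if(pseudocount < 0, "`pseudocount` must be non-negative")
  rng <- range(c(a, b))
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  ca <- tabulate(cut(a, breaks, include.lowest = TRUE, labels = FALSE),
                 nbins = bins) + pseudocount
  cb <- tabulate(cut(b, breaks, include.lowest = TRUE, labels = FALSE),
                 nbins = bins) + pseudocount
  p <- ca / sum(ca)
  q <- cb / sum(cb)
  sum(p * log(p / q))
}

#' Elastic stiffness from helical-parameter covariance
#'
#' Harmonic (quasi-elastic) force constants by covariance inversion:
#' `K = k_B T C^-1`, with C the covariance of the step parameters over
#' frames.  Near-singular covariances fall back to the Moore-Penrose
#' pseudo-inverse with a warning flag.
#'
#' @param series Long helical-parameter tibble ([helpar_extract()] /
#'   [simulate_helpar()]).
#' @param temperature Temperature in kelvin.
#' @param unit_type Unit class to analyse (default `"step"`).
#' @return A `stiffness_result`: long tibble `unit, par_row, par_col, k`
#'   (kJ/mol per unit^2) with attributes `matrices` (named list of 6x6
#'   matrices), `temperature` and `degenerate` (logical per unit).
#' @examples
#' sim <- simulate_helpar(diag(10, 2), n_frames = 2000, seed = 1)
#' stiffness_from_covariance(sim)
#' @export
stiffness_from_covariance <- function(series, temperature = 300,
                                      unit_type = "step") {
  units <- sort(unique(series$unit[series$unit_type == unit_type]))
  abort_if(length(units) == 0L, "no units of the requested type")
  kbt <- kBT_kJ(temperature)
  mats <- list()
  degenerate <- logical(0)
  rows <- list()
  for (u in units) {
    X <- helpar_wide(series, unit = u, unit_type = unit_type)
    abort_if(nrow(X) < 10L * ncol(X),
             "need at least 10x more frames than parameters")
    C <- stats::cov(X)
    if (rcond(C) < 1e-12) {
      warning("near-singular covariance for unit ", u,
              "; using pseudo-inverse", call. = FALSE)
      K <- kbt * MASS::ginv(C)
      degenerate <- c(degenerate, TRUE)
    } else {
      K <- kbt * solve(C)
      degenerate <- c(degenerate, FALSE)
    }
    K <- (K + t(K)) / 2
    dimnames(K) <- dimnames(C)
    mats[[as.character(u)]] <- K
    pn <- colnames(K)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      unit = u,
      par_row = rep(pn, times = length(pn)),
      par_col = rep(pn, each = length(pn)),
      k = as.vector(K)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stiffness_result", class(tibble::tibble()))
  attr(out, "matrices") <- mats
  attr(out, "temperature") <- temperature
  attr(out, "degenerate") <- stats::setNames(degenerate, names(mats))
  out
}

#' Pure (diagonal) force constants
#'
#' @param stiffness A `stiffness_result`.
#' @return Tibble `unit, parameter, k` of the diagonal constants.
#' @export
pure_force_constants <- function(stiffness) {
  d <- stiffness[stiffness$par_row == stiffness$par_col, , drop = FALSE]
  tibble::tibble(unit = d$unit, parameter = d$par_row, k = d$k)
}

#' Overall stiffness scalars
#'
#' Per-step scalar summaries of the diagonal force constants: the mean of
#' the translational constants, the mean of the rotational constants, their
#' combined plain mean, and a z-scored combined mean (each constant
#' standardized across steps before averaging; zero when a constant does not
#' vary across steps).  The molecule-level scalar is the mean of the
#' per-step values.
#'
#' @param stiffness A `stiffness_result`.
#' @param translations,rotations Parameter names contributing to each class.
#' @return List with `per_step` (tibble `unit, trans_mean, rot_mean,
#'   combined_mean, z_mean`) and `molecule` (named numeric of the same four
#'   summaries averaged over steps).
#' @export
overall_stiffness <- function(stiffness,
                              translations = c("shift", "slide", "rise"),
                              rotations = c("tilt", "roll", "twist")) {
  d <- pure_force_constants(stiffness)
  abort_if(nrow(d) == 0L, "empty stiffness input")
  zs <- d |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(z = if (dplyr::n() > 1L && stats::sd(.data$k) > 0) {
      (.data$k - mean(.data$k)) / stats::sd(.data$k)
    } else {
      0
    }) |>
    dplyr::ungroup()
  per_step <- zs |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      trans_mean = mean(.data$k[.data$parameter %in% translations]),
      rot_mean = mean(.data$k[.data$parameter %in% rotations]),
      combined_mean = mean(.data$k),
      z_mean = mean(.data$z),
      .groups = "drop"
    )
  molecule <- c(
    trans_mean = mean(per_step$trans_mean, na.rm = TRUE),
    rot_mean = mean(per_step$rot_mean, na.rm = TRUE),
    combined_mean = mean(per_step$combined_mean),
    z_mean = mean(per_step$z_mean)
  )
  list(per_step = per_step, molecule = molecule)
}
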