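# Cambridge-convention helical parameters via the symmetric mid-frame
# construction: translations are projected onto the mid-frame axes and the
# relative rotation is decomposed into a twist about the mean normal plus a
# bend (roll/tilt) about the hinge axis.

HELPAR_STEP <- c("shift", "slide", "rise", "tilt", "roll", "twist")
HELPAR_INTRA <- c("shear", "stretch", "stagger", "buckle", "propeller",
                  "opening")

# Six parameters (tx, ty, tz, rot_x, rot_y, rot_z[deg]) between two frames.
mid_frame_params <- function(o1, T1, o2, T2) {
  z1 <- T1[, 3L]; z2 <- T2[, 3L]
  hinge <- cross3(z1, z2)
  nh <- vnorm(hinge)
  gamma <- atan2(nh, sum(z1 * z2))
  if (nh < 1e-12) {
    T1p <- T1; T2p <- T2
  } else {
    h <- hinge / nh
    T1p <- rotation_matrix(h, gamma / 2) %*% T1
    T2p <- rotation_matrix(h, -gamma / 2) %*% T2
  }
  zm <- unit_vec(T1p[, 3L] + T2p[, 3L])
  x1 <- T1p[, 1L]; x2 <- T2p[, 1L]
  twist <- atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2))
  Tm <- rotation_matrix(zm, twist / 2) %*% T1p
  trans <- drop(crossprod(Tm, o2 - o1))
  if (nh < 1e-12) {
    roll <- 0; tilt <- 0
  } else {
    h <- hinge / nh
    ym <- Tm[, 2L]
    phi <- atan2(sum(cross3(h, ym) * zm), sum(h * ym))
    roll <- gamma * cos(phi)
    tilt <- gamma * sin(phi)
  }
  c(trans, c(tilt, roll, twist) * 180 / pi)
}

# Inverse of mid_frame_params: frame 2 from frame 1 and six parameters.
# Used as an internal oracle for round-trip property tests.  Closed form in
# mid-frame coordinates: the hinge is h_m = (sin phi, cos phi, 0) with
# phi = atan2(tilt, roll), and T1 = Tm R(h_m, -G/2) R(e3, -w/2), so Tm
# follows from T1 directly.
mid_frame_reconstruct <- function(o1, T1, params) {
  tilt <- params[4L] * pi / 180
  roll <- params[5L] * pi / 180
  twist <- params[6L] * pi / 180
  gamma <- sqrt(tilt^2 + roll^2)
  e3 <- c(0, 0, 1)
  hm <- if (gamma < 1e-15) c(0, 1, 0) else
    c(sin(atan2(tilt, roll)), cos(atan2(tilt, roll)), 0)
  B1 <- rotation_matrix(hm, -gamma / 2) %*% rotation_matrix(e3, -twist / 2)
  B2 <- rotation_matrix(hm, gamma / 2) %*% rotation_matrix(e3, twist / 2)
  Tm <- T1 %*% t(B1)
  T2 <- Tm %*% B2
  o2 <- o1 + drop(Tm %*% params[1:3])
  list(o = o2, T = T2)
}

#' Extract helical parameters from base-pair frames
#'
#' Inter-base-pair step parameters (shift, slide, rise, tilt, roll, twist)
#' come from consecutive base-pair triads via the symmetric mid-frame
#' construction; intra-base-pair parameters (shear, stretch, stagger,
#' buckle, propeller, opening) from the Watson versus Crick base triads of
#' each pair.  Translations are in angstrom, rotations in degrees.
#'
#' @param frames Base-pair frame tibble from [compute_bp_frames()].
#' @param which One of `"both"`, `"step"`, `"intra"`.
#' @return Long tibble `frame, unit_type, unit, parameter, value`; for steps
#'   `unit` is the 5' level index of the step.
#' @export
helpar_extract <- function(frames, which = c("both", "step", "intra")) {
  which <- match.arg(which)
  out <- list()
  for (f in unique(frames$frame)) {
    fr <- frames[frames$frame == f, , drop = FALSE]
    fr <- fr[order(fr$level), , drop = FALSE]
    nlev <- nrow(fr)
    if (which != "intra") {
      abort_if(nlev < 2L, "need at least 2 base pairs for step parameters")
      for (i in seq_len(nlev - 1L)) {
        p <- mid_frame_params(frame_origin(fr[i, ]), frame_triad(fr[i, ]),
                              frame_origin(fr[i + 1L, ]),
                              frame_triad(fr[i + 1L, ]))
        out[[length(out) + 1L]] <- tibble::tibble(
          frame = f, unit_type = "step", unit = i,
          parameter = HELPAR_STEP, value = p
        )
      }
    }
    if (which != "step" && "w_ox" %in% names(fr)) {
      for (i in seq_len(nlev)) {
        p <- mid_frame_params(frame_origin(fr[i, ], "w_"),
                              frame_triad(fr[i, ], "w_"),
                              frame_origin(fr[i, ], "c_"),
                              frame_triad(fr[i, ], "c_"))
        out[[length(out) + 1L]] <- tibble::tibble(
          frame = f, unit_type = "bp", unit = i,
          parameter = HELPAR_INTRA, value = p
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Convert a long helical-parameter series to a frames-by-parameter matrix
#'
#' @param series Long tibble from [helpar_extract()] or [simulate_helpar()].
#' @param unit Unit (step or bp index) to extract.
#' @param unit_type `"step"` or `"bp"`.
#' @return Numeric matrix, one row per frame, one column per parameter.
#' @export
helpar_wide <- function(series, unit = 1L, unit_type = "step") {
  s <- series[series$unit == unit & series$unit_type == unit_type, ,
              drop = FALSE]
  abort_if(nrow(s) == 0L, "no rows for the requested unit")
  w <- tidyr::pivot_wider(s, id_cols = "frame", names_from = "parameter",
                          values_from = "value")
  as.matrix(w[, setdiff(names(w), "frame"), drop = FALSE])
}

#' Simulate helical-parameter fluctuations with known stiffness
#'
#' Samples a multivariate Gaussian with covariance `C = k_B T K^-1` centred
#' on the equilibrium values, the harmonic ground truth for stiffness
#' recovery.
#'
#' @param K Symmetric positive-definite stiffness matrix (kJ/mol per
#'   angstrom^2, per degree^2, or mixed).
#' @param means Equilibrium parameter values (defaults to zeros).
#' @param temperature Temperature in kelvin.
#' @param n_frames Number of frames (>= 2).
#' @param parameters Parameter names (defaults to the six step parameters or
#'   `colnames(K)`).
#' @param unit Unit index stored in the output.
#' @param seed Integer seed or NULL.
#' @return Long tibble `frame, unit_type, unit, parameter, value` with
#'   attribute `ground_truth = list(K, means, temperature)`.
#' @export
simulate_helpar <- function(K, means = NULL, temperature = 300,
                            n_frames = 1000L, parameters = NULL,
                            unit = 1L, seed = NULL) {
  K <- as.matrix(K)
  d <- nrow(K)
  abort_if(d != ncol(K) || max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))),
           "`K` must be square and symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev) <= 0, "`K` must be positive-definite")
  abort_if(n_frames < 2L, "`n_frames` must be >= 2")
  means <- means %||% rep(0, d)
  parameters <- parameters %||% colnames(K) %||%
    (if (d <= 6L) HELPAR_STEP[seq_len(d)] else paste0("p", seq_len(d)))
  C <- kBT_kJ(temperature) * solve(K)
  C <- (C + t(C)) / 2
  X <- with_seed_(seed, MASS::mvrnorm(n_frames, mu = means, Sigma = C))
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- parameters
  out$frame <- seq_len(n_frames)
  out <- tidyr::pivot_longer(out, -"frame", names_to = "parameter",
                             values_to = "value")
  out$unit_type <- "step"
  out$unit <- unit
  out <- out[, c("frame", "unit_type", "unit", "parameter", "value")]
  attr(out, "ground_truth") <- list(K = K, means = means,
                                    temperature = temperature)
  out
}
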