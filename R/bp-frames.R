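#' Base-pair frames from a duplex trajectory
#'
#' For every frame and every Watson-Crick pair, builds an orthonormal
#' right-handed base-pair triad: the origin is the midpoint of the two C1'
#' atoms, the y-axis points along Watson C1' -> Crick C1', the z-axis is the
#' local helical advance (direction of neighbouring base-pair origins,
#' orthogonalized against y) and x = y x z points toward the major groove.
#' Per-base triads for the Watson and Crick bases (used for intra-base-pair
#' parameters) are built from each base's own C1' and Watson-Crick edge
#' atoms, with the Crick triad flipped into the pairing convention so that
#' both triads coincide for ideal geometry.
#'
#' @param traj A [dna_trajectory()].
#' @param pairing Pairing table (see [dna_trajectory()]); defaults to the one
#'   stored in `traj`.
#' @return Tibble with one row per frame and level: origin (`ox,oy,oz`),
#'   base-pair triad columns (`xx..zz`, axis components by row vector), and
#'   Watson/Crick base triads (`w_*`, `c_*`).
#' @export
compute_bp_frames <- function(traj, pairing = NULL) {
  pairing <- pairing %||% traj$pairing
  abort_if(is.null(pairing), "no pairing table available")
  nlev <- nrow(pairing)
  at <- traj$atoms

  find_atom <- function(chain, resid, name) {
    i <- which(at$chain == chain & at$resid == resid & at$name == name)
    abort_if(length(i) == 0L,
             paste0("missing atom ", name, " in residue ", chain, ":", resid))
    i[1L]
  }
  edge_atoms <- function(chain, resid) {
    resname <- at$resname[at$chain == chain & at$resid == resid][1L]
    nm <- union(WC_DONORS[[resname]], WC_ACCEPTORS[[resname]])
    idx <- which(at$chain == chain & at$resid == resid & at$name %in% nm)
    abort_if(length(idx) == 0L,
             paste0("missing WC edge atoms in residue ", chain, ":", resid))
    idx
  }

  w_c1 <- purrr::map_int(seq_len(nlev), ~find_atom(pairing$watson_chain[.x],
                                                   pairing$watson_resid[.x], "C1'"))
  c_c1 <- purrr::map_int(seq_len(nlev), ~find_atom(pairing$crick_chain[.x],
                                                   pairing$crick_resid[.x], "C1'"))
  w_edge <- purrr::map(seq_len(nlev), ~edge_atoms(pairing$watson_chain[.x],
                                                  pairing$watson_resid[.x]))
  c_edge <- purrr::map(seq_len(nlev), ~edge_atoms(pairing$crick_chain[.x],
                                                  pairing$crick_resid[.x]))

  one_frame <- function(f) {
    xyz <- frame_coords(traj, f)
    ow <- xyz[w_c1, , drop = FALSE]
    oc <- xyz[c_c1, , drop = FALSE]
    origin <- (ow + oc) / 2
    # helical tangent at each level from neighbouring origins
    tang <- matrix(0, nlev, 3L)
    tang[1L, ] <- origin[2L, ] - origin[1L, ]
    tang[nlev, ] <- origin[nlev, ] - origin[nlev - 1L, ]
    if (nlev > 2L) {
      tang[2:(nlev - 1L), ] <- origin[3:nlev, , drop = FALSE] -
        origin[1:(nlev - 2L), , drop = FALSE]
    }

    build_triad <- function(yv, tv) {
      y <- unit_vec(yv)
      zr <- tv - sum(tv * y) * y
      abort_if(vnorm(zr) < 1e-9, "degenerate (collinear) base-pair geometry")
      z <- unit_vec(zr)
      x <- cross3(y, z)
      cbind(x, y, z)
    }

    purrr::map_dfr(seq_len(nlev), function(i) {
      Tbp <- build_triad(oc[i, ] - ow[i, ], tang[i, ])
      ew <- colMeans(xyz[w_edge[[i]], , drop = FALSE])
      ec <- colMeans(xyz[c_edge[[i]], , drop = FALSE])
      Tw <- build_triad(ew - ow[i, ], tang[i, ])
      Tc <- build_triad(oc[i, ] - ec, tang[i, ])
      # base origins: edge centroid advanced by half the H-bond length so
      # that paired origins coincide in ideal geometry
      wo <- ew + EDGE_Y * Tw[, 2L]
      co <- ec - EDGE_Y * Tc[, 2L]
      tibble::tibble(
        frame = f, level = i,
        ox = origin[i, 1L], oy = origin[i, 2L], oz = origin[i, 3L],
        xx = Tbp[1L, 1L], xy = Tbp[2L, 1L], xz = Tbp[3L, 1L],
        yx = Tbp[1L, 2L], yy = Tbp[2L, 2L], yz = Tbp[3L, 2L],
        zx = Tbp[1L, 3L], zy = Tbp[2L, 3L], zz = Tbp[3L, 3L],
        w_ox = wo[1L], w_oy = wo[2L], w_oz = wo[3L],
        w_xx = Tw[1L, 1L], w_xy = Tw[2L, 1L], w_xz = Tw[3L, 1L],
        w_yx = Tw[1L, 2L], w_yy = Tw[2L, 2L], w_yz = Tw[3L, 2L],
        w_zx = Tw[1L, 3L], w_zy = Tw[2L, 3L], w_zz = Tw[3L, 3L],
        c_ox = co[1L], c_oy = co[2L], c_oz = co[3L],
        c_xx = Tc[1L, 1L], c_xy = Tc[2L, 1L], c_xz = Tc[3L, 1L],
        c_yx = Tc[1L, 2L], c_yy = Tc[2L, 2L], c_yz = Tc[3L, 2L],
        c_zx = Tc[1L, 3L], c_zy = Tc[2L, 3L], c_zz = Tc[3L, 3L]
      )
    })
  }

  purrr::map_dfr(seq_len(n_frames(traj)), one_frame)
}

# Extract origin / triad matrices for one row of a bp-frame tibble.
frame_origin <- function(row, prefix = "") {
  c(row[[paste0(prefix, "ox")]], row[[paste0(prefix, "oy")]],
    row[[paste0(prefix, "oz")]])
}
frame_triad <- function(row, prefix = "") {
  cbind(
    c(row[[paste0(prefix, "xx")]], row[[paste0(prefix, "xy")]], row[[paste0(prefix, "xz")]]),
    c(row[[paste0(prefix, "yx")]], row[[paste0(prefix, "yy")]], row[[paste0(prefix, "yz")]]),
    c(row[[paste0(prefix, "zx")]], row[[paste0(prefix, "zy")]], row[[paste0(prefix, "zz")]])
  )
}

new_helical_axis <- function(points) {
  n <- nrow(points)
  tang <- matrix(0, n, 3L)
  tang[1L, ] <- points[2L, ] - points[1L, ]
  tang[n, ] <- points[n, ] - points[n - 1L, ]
  if (n > 2L) {
    tang[2:(n - 1L), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2L), , drop = FALSE]
  }
  tang <- t(apply(tang, 1L, unit_vec))
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  out <- tibble::tibble(
    level = seq_len(n),
    x = points[, 1L], y = points[, 2L], z = points[, 3L],
    tx = tang[, 1L], ty = tang[, 2L], tz = tang[, 3L],
    arclength = c(0, cumsum(seg))
  )
  class(out) <- c("helical_axis", class(tibble::tibble()))
  out
}

#' Fit an instantaneous helical axis through base-pair origins
#'
#' The axis points are the base-pair origins smoothed with a cubic smoothing
#' spline along the base-pair index (one spline per coordinate); tangents are
#' normalized central differences and arclength accumulates chord lengths.
#' This is a smoothing-spline stand-in for an optimal-axis algorithm; all
#' helicoidal analyses in this package use the same convention on both the
#' forward and inverse mapping, so results are internally consistent.
#'
#' @param frames Base-pair frame tibble from [compute_bp_frames()] for a
#'   single frame (filter first, or pass `frame`).
#' @param frame Optional frame index to select from a multi-frame tibble.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]; NULL
#'   uses generalized cross-validation (noiseless input is reproduced).
#' @return A `helical_axis` tibble: per-level axis `x,y,z`, unit tangents
#'   `tx,ty,tz` and cumulative `arclength` (angstrom).
#' @export
fit_helical_axis <- function(frames, frame = NULL, spar = NULL) {
  if (!is.null(frame)) frames <- frames[frames$frame == frame, , drop = FALSE]
  abort_if(length(unique(frames$frame)) != 1L,
           "`frames` spans several frames; select one with `frame`")
  n <- nrow(frames)
  abort_if(n < 4L, "need at least 4 base pairs to fit an axis")
  pts <- as.matrix(frames[, c("ox", "oy", "oz")])
  idx <- frames$level
  sm <- function(yv) {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(idx, yv)
    } else {
      stats::smooth.spline(idx, yv, spar = spar)
    }
    stats::predict(fit, idx)$y
  }
  new_helical_axis(cbind(sm(pts[, 1L]), sm(pts[, 2L]), sm(pts[, 3L])))
}

#' Helical axis without smoothing
#'
#' Polyline through the base-pair origins exactly (no spline); useful for
#' synthetic round-trip work on ideal geometry.
#'
#' @inheritParams fit_helical_axis
#' @return A `helical_axis` tibble.
#' @export
axis_from_frames <- function(frames, frame = NULL) {
  if (!is.null(frame)) frames <- frames[frames$frame == frame, , drop = FALSE]
  abort_if(length(unique(frames$frame)) != 1L,
           "`frames` spans several frames; select one with `frame`")
  abort_if(nrow(frames) < 2L, "need at least 2 base pairs")
  new_helical_axis(as.matrix(frames[, c("ox", "oy", "oz")]))
}
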