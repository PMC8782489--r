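#' Groove / radius region definitions
#'
#' Angular and radial boundaries used to partition the space around a duplex:
#' the minor groove spans azimuths 33-147 degrees (half-open), the inner
#' groove space reaches 10.25 angstrom from the axis and the total radial
#' cutoff is 20.5 angstrom.
#'
#' @param minor_lo,minor_hi Minor-groove azimuth window, degrees.
#' @param inner_R Inner-region radius, angstrom.
#' @param cutoff_R Total radial cutoff, angstrom.
#' @return A `region_spec` list.
#' @export
region_spec <- function(minor_lo = 33, minor_hi = 147,
                        inner_R = 10.25, cutoff_R = 20.5) {
  abort_if(!(0 <= minor_lo && minor_lo < minor_hi && minor_hi < 360),
           "need 0 <= minor_lo < minor_hi < 360")
  abort_if(!(0 < inner_R && inner_R < cutoff_R),
           "need 0 < inner_R < cutoff_R")
  structure(list(minor_lo = minor_lo, minor_hi = minor_hi,
                 inner_R = inner_R, cutoff_R = cutoff_R),
            class = "region_spec")
}

# Projected, renormalized frame axes perpendicular to the tangent, per level.
level_angle_axes <- function(axis, frames) {
  n <- nrow(axis)
  xs <- matrix(0, n, 3L); ys <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    tv <- c(axis$tx[i], axis$ty[i], axis$tz[i])
    row <- frames[i, ]
    xv <- c(row$xx, row$xy, row$xz)
    yv <- c(row$yx, row$yy, row$yz)
    xs[i, ] <- unit_vec(xv - sum(xv * tv) * tv)
    ys[i, ] <- unit_vec(yv - sum(yv * tv) * tv)
  }
  list(x = xs, y = ys)
}

#' Map particles into curvilinear helicoidal coordinates
#'
#' Each particle is projected onto the helical axis polyline; `D` is the
#' arclength at the foot point, `R` the perpendicular distance to the axis
#' and `A` the azimuth of the radial vector in the plane normal to the local
#' tangent.  `A` is measured from the base-pair y-axis increasing toward the
#' minus-x (minor groove) direction, so the minor groove of canonical B-DNA
#' is centred near 90 degrees and falls inside the 33-147 degree window.
#' Particles closer than 1e-9 angstrom to the axis get the sentinel
#' `R = 0, A = 0`.
#'
#' @param axis A `helical_axis` (same frame as `coords`).
#' @param frames Base-pair frame tibble for the same frame (angle reference).
#' @param coords Numeric matrix `m x 3` of particle positions.
#' @return Tibble with columns `D`, `R`, `A` (degrees in `[0, 360)`), with
#'   the duplex arclength span attached as attribute `d_span`.
#' @export
to_helicoidal <- function(axis, frames, coords) {
  abort_if(nrow(axis) < 2L, "axis needs at least 2 points")
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  m <- nrow(coords)
  pts <- as.matrix(axis[, c("x", "y", "z")])
  n <- nrow(pts)
  arc <- axis$arclength

  a <- pts[-n, , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)

  best_d2 <- rep(Inf, m); best_seg <- integer(m); best_t <- numeric(m)
  for (s in seq_len(n - 1L)) {
    pa <- sweep(coords, 2L, a[s, ])
    t <- pmin(1, pmax(0, as.vector(pa %*% ab[s, ]) / len2[s]))
    foot <- outer(t, ab[s, ]) + matrix(a[s, ], m, 3L, byrow = TRUE)
    d2 <- rowSums((coords - foot)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_seg[upd] <- s; best_t[upd] <- t[upd]
  }

  seg_len <- sqrt(len2)
  foot <- a[best_seg, , drop = FALSE] + ab[best_seg, , drop = FALSE] * best_t
  rad <- coords - foot
  # axial offset along the segment direction: zero for interior projections,
  # the signed overhang for particles beyond the end caps, so that D runs
  # beyond the duplex span there (and such particles classify as bulk)
  axial <- rowSums(rad * (ab[best_seg, , drop = FALSE] / seg_len[best_seg]))
  D <- arc[best_seg] + best_t * seg_len[best_seg] + axial
  # nearest level (by arclength) supplies tangent and angle reference
  lev <- ifelse(D - arc[best_seg] < arc[best_seg + 1L] - D,
                best_seg, best_seg + 1L)
  lev <- pmin(pmax(lev, 1L), n)
  axes <- level_angle_axes(axis, frames)
  tv <- as.matrix(axis[, c("tx", "ty", "tz")])

  R <- numeric(m); A <- numeric(m)
  for (i in seq_len(m)) {
    l <- lev[i]
    r <- rad[i, ]
    r <- r - sum(r * tv[l, ]) * tv[l, ]
    R[i] <- vnorm(r)
    if (R[i] < 1e-9) {
      R[i] <- 0; A[i] <- 0
    } else {
      u <- r / R[i]
      A[i] <- wrap_angle_deg(atan2(-sum(u * axes$x[l, ]),
                                   sum(u * axes$y[l, ])) * 180 / pi)
    }
  }
  out <- tibble::tibble(D = D, R = R, A = A)
  attr(out, "d_span") <- c(arc[1L], arc[n])
  out
}

#' Place a point at given helicoidal coordinates
#'
#' Inverse of [to_helicoidal()] under the same conventions (exact on a
#' straight axis).
#'
#' @inheritParams to_helicoidal
#' @param D,R,A Helicoidal coordinates (vectors of equal length; `A` in
#'   degrees).
#' @return `m x 3` matrix of Cartesian positions.
#' @export
place_helicoidal <- function(axis, frames, D, R, A) {
  pts <- as.matrix(axis[, c("x", "y", "z")])
  n <- nrow(pts)
  arc <- axis$arclength
  axes <- level_angle_axes(axis, frames)
  m <- length(D)
  out <- matrix(0, m, 3L)
  for (i in seq_len(m)) {
    d <- min(max(D[i], arc[1L]), arc[n])
    s <- findInterval(d, arc, rightmost.closed = TRUE)
    s <- min(max(s, 1L), n - 1L)
    t <- (d - arc[s]) / (arc[s + 1L] - arc[s])
    foot <- pts[s, ] + t * (pts[s + 1L, ] - pts[s, ])
    l <- if (d - arc[s] < arc[s + 1L] - d) s else s + 1L
    ar <- A[i] * pi / 180
    u <- cos(ar) * axes$y[l, ] - sin(ar) * axes$x[l, ]
    out[i, ] <- foot + R[i] * u
  }
  out
}

#' Assign groove / radial region labels
#'
#' Total function on helicoidal coordinates: minor iff `A` in `[33, 147)`
#' (half-open), inner iff `R <= 10.25`, outer iff `10.25 < R <= 20.5`, bulk
#' iff `R > 20.5` or `D` outside the duplex span.
#'
#' @param hcoords Tibble with columns `D`, `R`, `A` (e.g. from
#'   [to_helicoidal()]).
#' @param spec A [region_spec()].
#' @param d_span Length-2 numeric duplex arclength span; defaults to the
#'   `d_span` attribute of `hcoords`, and to no D filtering when absent.
#' @return `hcoords` with a `region` factor column added (levels
#'   `minor_inner`, `major_inner`, `minor_outer`, `major_outer`, `bulk`).
#' @export
assign_region <- function(hcoords, spec = region_spec(),
                          d_span = attr(hcoords, "d_span")) {
  minor <- hcoords$A >= spec$minor_lo & hcoords$A < spec$minor_hi
  inner <- hcoords$R <= spec$inner_R
  outer <- hcoords$R > spec$inner_R & hcoords$R <= spec$cutoff_R
  in_span <- if (is.null(d_span)) TRUE else
    hcoords$D >= d_span[1L] & hcoords$D <= d_span[2L]
  region <- dplyr::case_when(
    !in_span | hcoords$R > spec$cutoff_R ~ "bulk",
    minor & inner ~ "minor_inner",
    !minor & inner ~ "major_inner",
    minor & outer ~ "minor_outer",
    TRUE ~ "major_outer"
  )
  hcoords$region <- factor(region, levels = c("minor_inner", "major_inner",
                                              "minor_outer", "major_outer",
                                              "bulk"))
  hcoords
}

# counts -> mol/L for a cell volume in cubic angstrom
molarity_from_count <- function(count, volume_A3) {
  count / (phys_constants()$N_A * volume_A3 * 1e-27)
}

#' Molarity-normalized radial-angular density map
#'
#' Bins helicoidal coordinates on an `(R, A)` grid (arclength integrated over
#' the duplex span) and converts mean per-frame counts into molarity using
#' the curvilinear cell volume `dD * R_mid * dR * dA(rad)`.  The bulk
#' molarity comes from particles beyond the radial cutoff using the box
#' volume minus the cutoff cylinder.
#'
#' @param hcoords Tibble with columns `frame`, `D`, `R`, `A`.
#' @param r_breaks,a_breaks Bin edges in angstrom / degrees.
#' @param d_span Duplex arclength span (defaults to the tibble attribute).
#' @param box_volume Periodic box volume in cubic angstrom (needed for the
#'   bulk molarity; NA otherwise).
#' @param n_frames Number of frames (defaults to `max(frame)` so that empty
#'   frames at the end are not silently dropped).
#' @return A `density_map` tibble: `r_lo, r_hi, a_lo, a_hi, r_mid, a_mid,
#'   mean_count, molarity`, with attributes `bulk_molarity`, `d_span`,
#'   `cell_volume`.
#' @export
density_map <- function(hcoords, r_breaks = seq(0, 20.5, by = 2.05),
                        a_breaks = seq(0, 360, by = 30),
                        d_span = attr(hcoords, "d_span"),
                        box_volume = NULL, n_frames = NULL) {
  abort_if(is.null(hcoords$frame), "`hcoords` needs a `frame` column")
  abort_if(is.null(d_span), "`d_span` is required (attribute or argument)")
  n_frames <- n_frames %||% max(hcoords$frame)
  dd <- d_span[2L] - d_span[1L]
  abort_if(dd <= 0, "zero-length duplex span gives zero-volume cells")
  abort_if(any(diff(r_breaks) <= 0) || any(diff(a_breaks) <= 0),
           "bin edges must be increasing")

  inside <- hcoords$R <= max(r_breaks) & hcoords$R >= min(r_breaks) &
    hcoords$D >= d_span[1L] & hcoords$D <= d_span[2L]
  hin <- hcoords[inside, , drop = FALSE]
  ri <- cut(hin$R, r_breaks, include.lowest = TRUE, labels = FALSE)
  ai <- cut(hin$A, a_breaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ri) & !is.na(ai)
  counts <- table(factor(ri[keep], levels = seq_len(length(r_breaks) - 1L)),
                  factor(ai[keep], levels = seq_len(length(a_breaks) - 1L)))

  grid <- tidyr::expand_grid(
    r_bin = seq_len(length(r_breaks) - 1L),
    a_bin = seq_len(length(a_breaks) - 1L)
  )
  grid$r_lo <- r_breaks[grid$r_bin]
  grid$r_hi <- r_breaks[grid$r_bin + 1L]
  grid$a_lo <- a_breaks[grid$a_bin]
  grid$a_hi <- a_breaks[grid$a_bin + 1L]
  grid$r_mid <- (grid$r_lo + grid$r_hi) / 2
  grid$a_mid <- (grid$a_lo + grid$a_hi) / 2
  grid$mean_count <- as.vector(counts[cbind(grid$r_bin, grid$a_bin)]) / n_frames
  grid$cell_volume <- dd * grid$r_mid * (grid$r_hi - grid$r_lo) *
    (grid$a_hi - grid$a_lo) * pi / 180
  abort_if(any(grid$cell_volume <= 0), "zero-volume density cell")
  grid$molarity <- molarity_from_count(grid$mean_count, grid$cell_volume)

  bulk_molarity <- NA_real_
  if (!is.null(box_volume)) {
    v_bulk <- box_volume - pi * max(r_breaks)^2 * dd
    abort_if(v_bulk <= 0, "box volume smaller than the cutoff cylinder")
    n_bulk <- sum(!inside) / n_frames
    bulk_molarity <- molarity_from_count(n_bulk, v_bulk)
  }

  out <- grid[, c("r_lo", "r_hi", "a_lo", "a_hi", "r_mid", "a_mid",
                  "mean_count", "cell_volume", "molarity")]
  class(out) <- c("density_map", class(tibble::tibble()))
  attr(out, "bulk_molarity") <- bulk_molarity
  attr(out, "d_span") <- d_span
  out
}

#' Groove enrichment relative to the bulk
#'
#' Per-cell molarity divided by the bulk molarity, plus the maximum ratio
#' (the paper-style "fold over bulk" number).
#'
#' @param map A `density_map` with a positive bulk molarity.
#' @return The map with a `ratio` column; the maximum ratio is attached as
#'   attribute `max_ratio`.
#' @export
bulk_ratio <- function(map) {
  bm <- attr(map, "bulk_molarity")
  abort_if(is.null(bm) || is.na(bm) || bm <= 0,
           "bulk molarity is zero or unknown; supply `box_volume` to density_map()")
  map$ratio <- map$molarity / bm
  attr(map, "max_ratio") <- max(map$ratio)
  map
}

#' Convergence of region occupancy over frames
#'
#' Running mean of per-frame particle counts in one region, plus 10-block
#' averages with standard errors and a drift flag comparing the first and
#' last block.
#'
#' @param hcoords Tibble with `frame` and `region` columns (see
#'   [assign_region()]).
#' @param region Region label to follow.
#' @param n_blocks Number of blocks for the block averages.
#' @return List with `series` (tibble `frame`, `count`, `running_mean`),
#'   `blocks` (tibble `block`, `mean`, `se`) and `drift_flag` (TRUE when the
#'   first/last block means differ by more than 3 pooled standard errors).
#' @export
convergence_series <- function(hcoords, region = "minor_inner",
                               n_blocks = 10L) {
  abort_if(is.null(hcoords$region), "run assign_region() first")
  frames <- sort(unique(hcoords$frame))
  abort_if(length(frames) < 10L, "need at least 10 frames")
  counts <- purrr::map_int(frames, function(f) {
    sum(hcoords$frame == f & hcoords$region == region)
  })
  series <- tibble::tibble(
    frame = frames,
    count = counts,
    running_mean = cumsum(counts) / seq_along(counts)
  )
  blk <- cut(seq_along(frames), n_blocks, labels = FALSE)
  blocks <- tibble::tibble(block = seq_len(n_blocks)) |>
    dplyr::mutate(
      mean = purrr::map_dbl(.data$block, ~mean(counts[blk == .x])),
      se = purrr::map_dbl(.data$block,
                          ~stats::sd(counts[blk == .x]) /
                            sqrt(sum(blk == .x)))
    )
  se_pool <- sqrt(sum(blocks$se[c(1L, n_blocks)]^2, na.rm = TRUE))
  drift <- abs(blocks$mean[n_blocks] - blocks$mean[1L]) >
    3 * max(se_pool, 1e-12)
  list(series = series, blocks = blocks, drift_flag = drift)
}

#' Radial molarity profile, split by groove
#'
#' Shell-volume-normalized molarity versus distance from the axis, computed
#' separately for the minor- and major-groove azimuth sectors.
#'
#' @param hcoords Tibble with `frame`, `D`, `R`, `A`.
#' @param dr Radial bin width, angstrom (> 0).
#' @param spec A [region_spec()] providing the groove window and cutoff.
#' @param d_span Duplex span (defaults to the attribute).
#' @param r_max Maximum radius of the profile (default: inner radius, as in
#'   groove-focused radial distribution plots).
#' @param n_frames Number of frames (default `max(frame)`).
#' @return Tibble `groove`, `r_lo`, `r_hi`, `r_mid`, `mean_count`,
#'   `molarity`.
#' @export
radial_distribution <- function(hcoords, dr = 0.5, spec = region_spec(),
                                d_span = attr(hcoords, "d_span"),
                                r_max = spec$inner_R, n_frames = NULL) {
  abort_if(dr <= 0, "`dr` must be positive")
  abort_if(is.null(d_span), "`d_span` is required")
  n_frames <- n_frames %||% max(hcoords$frame)
  dd <- d_span[2L] - d_span[1L]
  breaks <- seq(0, r_max, by = dr)
  if (max(breaks) < r_max) breaks <- c(breaks, r_max)
  minor <- hcoords$A >= spec$minor_lo & hcoords$A < spec$minor_hi
  in_span <- hcoords$D >= d_span[1L] & hcoords$D <= d_span[2L]
  minor_frac <- (spec$minor_hi - spec$minor_lo) / 360

  one_groove <- function(sel, frac, label) {
    h <- hcoords[sel & in_span & hcoords$R <= r_max, , drop = FALSE]
    bi <- cut(h$R, breaks, include.lowest = TRUE, labels = FALSE)
    cnt <- tabulate(bi, nbins = length(breaks) - 1L) / n_frames
    vol <- dd * frac * pi * (breaks[-1L]^2 - breaks[-length(breaks)]^2)
    tibble::tibble(
      groove = label,
      r_lo = breaks[-length(breaks)], r_hi = breaks[-1L],
      r_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
      mean_count = cnt,
      molarity = molarity_from_count(cnt, vol)
    )
  }
  dplyr::bind_rows(
    one_groove(minor, minor_frac, "minor"),
    one_groove(!minor, 1 - minor_frac, "major")
  )
}
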