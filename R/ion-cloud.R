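#' Simulate an ion cloud around a duplex axis
#'
#' Generates per-frame ion positions whose regional concentrations match
#' target molarities.  For each groove region the per-frame count is Poisson
#' with mean `molarity * N_A * V_region` (V from the curvilinear region
#' volume) and positions are uniform within the region (uniform in D, in the
#' azimuth window, and in R weighted by the annular area).  Bulk ions are
#' uniform in the periodic box outside the radial cutoff.
#'
#' @param axis A `helical_axis` (e.g. from [axis_from_frames()]).
#' @param frames Matching base-pair frame tibble (angle reference).
#' @param region_molarity Named numeric of target molarities (mol/L) for any
#'   of `minor_inner`, `major_inner`, `minor_outer`, `major_outer`.
#' @param bulk_molarity Molarity outside the cutoff cylinder.
#' @param box Length-3 box dimensions in angstrom (centred on the axis
#'   midpoint); required when `bulk_molarity > 0`.
#' @param n_frames Number of frames.
#' @param spec A [region_spec()].
#' @param seed Integer seed or NULL.
#' @return Tibble `frame, x, y, z, region_intended` with attributes `d_span`
#'   and `box`.
#' @export
simulate_ion_cloud <- function(axis, frames, region_molarity = c(),
                               bulk_molarity = 0, box = NULL,
                               n_frames = 1L, spec = region_spec(),
                               seed = NULL) {
  abort_if(nrow(axis) < 2L, "axis needs at least 2 points")
  abort_if(any(region_molarity < 0) || bulk_molarity < 0,
           "molarities must be non-negative")
  known <- c("minor_inner", "major_inner", "minor_outer", "major_outer")
  abort_if(length(region_molarity) > 0 && !all(names(region_molarity) %in% known),
           paste0("region names must be among: ", paste(known, collapse = ", ")))
  d_lo <- axis$arclength[1L]
  d_hi <- axis$arclength[nrow(axis)]
  dd <- d_hi - d_lo
  abort_if(dd <= 0, "zero-length axis span gives zero region volumes")
  NA_ <- phys_constants()$N_A

  minor_w <- spec$minor_hi - spec$minor_lo
  geom <- list(
    minor_inner = list(a = c(spec$minor_lo, spec$minor_hi), r = c(0, spec$inner_R)),
    major_inner = list(a = c(spec$minor_hi, spec$minor_lo + 360), r = c(0, spec$inner_R)),
    minor_outer = list(a = c(spec$minor_lo, spec$minor_hi), r = c(spec$inner_R, spec$cutoff_R)),
    major_outer = list(a = c(spec$minor_hi, spec$minor_lo + 360), r = c(spec$inner_R, spec$cutoff_R))
  )

  with_seed_(seed, {
    parts <- list()
    for (nm in names(region_molarity)) {
      g <- geom[[nm]]
      vol <- dd * (g$a[2L] - g$a[1L]) * pi / 180 / 2 * (g$r[2L]^2 - g$r[1L]^2)
      lambda <- region_molarity[[nm]] * NA_ * vol * 1e-27
      for (f in seq_len(n_frames)) {
        cnt <- stats::rpois(1L, lambda)
        if (cnt == 0L) next
        d <- stats::runif(cnt, d_lo, d_hi)
        a <- wrap_angle_deg(stats::runif(cnt, g$a[1L], g$a[2L]))
        r <- sqrt(stats::runif(cnt, g$r[1L]^2, g$r[2L]^2))
        pos <- place_helicoidal(axis, frames, d, r, a)
        parts[[length(parts) + 1L]] <- tibble::tibble(
          frame = f, x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
          region_intended = nm
        )
      }
    }

    if (bulk_molarity > 0) {
      abort_if(is.null(box) || length(box) != 3L,
               "`box` (length 3) is required for bulk ions")
      v_bulk <- prod(box) - pi * spec$cutoff_R^2 * dd
      abort_if(v_bulk <= 0, "box smaller than the cutoff cylinder")
      centre <- colMeans(as.matrix(axis[, c("x", "y", "z")]))
      lambda <- bulk_molarity * NA_ * v_bulk * 1e-27
      for (f in seq_len(n_frames)) {
        cnt <- stats::rpois(1L, lambda)
        got <- matrix(numeric(0), 0L, 3L)
        while (nrow(got) < cnt) {
          m <- max(2L * (cnt - nrow(got)), 16L)
          cand <- cbind(stats::runif(m, -box[1L] / 2, box[1L] / 2),
                        stats::runif(m, -box[2L] / 2, box[2L] / 2),
                        stats::runif(m, -box[3L] / 2, box[3L] / 2))
          cand <- sweep(cand, 2L, centre, `+`)
          hc <- to_helicoidal(axis, frames, cand)
          outside <- hc$R > spec$cutoff_R | hc$D < d_lo | hc$D > d_hi
          got <- rbind(got, cand[outside, , drop = FALSE])
        }
        got <- got[seq_len(cnt), , drop = FALSE]
        if (cnt > 0L) {
          parts[[length(parts) + 1L]] <- tibble::tibble(
            frame = f, x = got[, 1L], y = got[, 2L], z = got[, 3L],
            region_intended = "bulk"
          )
        }
      }
    }

    out <- if (length(parts)) dplyr::bind_rows(parts) else
      tibble::tibble(frame = integer(), x = numeric(), y = numeric(),
                     z = numeric(), region_intended = character())
    attr(out, "d_span") <- c(d_lo, d_hi)
    attr(out, "box") <- box
    attr(out, "n_frames") <- n_frames
    out
  })
}

#' Map an ion cloud (or any particle table) into helicoidal coordinates
#'
#' Convenience wrapper applying [to_helicoidal()] frame-wise to a tibble of
#' particle positions around a fixed axis.
#'
#' @param particles Tibble with columns `frame, x, y, z`.
#' @inheritParams to_helicoidal
#' @return Tibble `frame, D, R, A` with the `d_span` attribute set.
#' @export
map_particles <- function(particles, axis, frames) {
  hc <- to_helicoidal(axis, frames,
                      as.matrix(particles[, c("x", "y", "z")]))
  out <- dplyr::bind_cols(particles[, "frame", drop = FALSE], hc)
  attr(out, "d_span") <- attr(hc, "d_span")
  out
}
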