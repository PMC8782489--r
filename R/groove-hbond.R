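#' Groove widths from cross-strand phosphate distances
#'
#' Minor- and major-groove widths by the phosphate-distance proxy: at each
#' level i the minor width is the minimum over a window of cross-strand
#' level offsets of the Watson P(i) to Crick P(j) distance, minus a 5.8
#' angstrom phosphate-radius correction; the major width uses the opposing
#' offset window.  Offsets are in level indexing (Watson 5'->3'); the minor
#' window `+1..+4` corresponds to the conventional strand-II offsets
#' i-3..i-1 in that strand's own 5'->3' numbering.  Terminal levels lacking
#' the full window are skipped.
#'
#' @param traj A [dna_trajectory()] with phosphate atoms.
#' @param pairing Pairing table (defaults to the trajectory's).
#' @param minor_offsets,major_offsets Cross-strand level-offset windows.
#' @param p_correction Phosphate-radius correction, angstrom.
#' @return Tibble `frame, level, minor_width, major_width` (angstrom; NA
#'   when a window leaves the duplex).
#' @export
groove_widths <- function(traj, pairing = NULL,
                          minor_offsets = 1:4, major_offsets = -(3:7),
                          p_correction = 5.8) {
  pairing <- pairing %||% traj$pairing
  abort_if(is.null(pairing), "no pairing table available")
  at <- traj$atoms
  nlev <- nrow(pairing)
  p_idx <- function(chain, resid) {
    i <- which(at$chain == chain & at$resid == resid & at$name == "P")
    if (length(i) == 0L) NA_integer_ else i[1L]
  }
  pw <- purrr::map_int(seq_len(nlev),
                       ~p_idx(pairing$watson_chain[.x], pairing$watson_resid[.x]))
  pc <- purrr::map_int(seq_len(nlev),
                       ~p_idx(pairing$crick_chain[.x], pairing$crick_resid[.x]))
  interior <- which(!is.na(pw))[which(!is.na(pw)) > 1L &
                                  which(!is.na(pw)) < nlev]
  abort_if(any(is.na(pw[2:(nlev - 1L)])) || any(is.na(pc[2:(nlev - 1L)])),
           "missing phosphates beyond the terminal levels")

  width_at <- function(xyz, i, offsets) {
    js <- i + offsets
    js <- js[js >= 1L & js <= nlev & !is.na(pc[pmax(pmin(js, nlev), 1L)])]
    if (length(js) < length(offsets)) return(NA_real_)
    dmin <- min(sqrt(rowSums((xyz[pc[js], , drop = FALSE] -
                                matrix(xyz[pw[i], ], length(js), 3L,
                                       byrow = TRUE))^2)))
    dmin - p_correction
  }

  purrr::map_dfr(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    purrr::map_dfr(seq_len(nlev), function(i) {
      if (is.na(pw[i])) return(NULL)
      tibble::tibble(
        frame = f, level = i,
        minor_width = width_at(xyz, i, minor_offsets),
        major_width = width_at(xyz, i, major_offsets)
      )
    })
  })
}

#' Count Watson-Crick hydrogen bonds per frame
#'
#' Counts cross-strand donor-acceptor contacts meeting a distance criterion
#' and a pseudo-linearity criterion (the angle at the donor between its
#' anchor C1' and the acceptor must exceed `angle_min`, a stand-in for the
#' D-H...A angle in this H-free coarse representation).
#'
#' @param traj A [dna_trajectory()] with WC edge atoms.
#' @param d_max Maximum donor-acceptor distance, angstrom.
#' @param angle_min Minimum anchor-donor-acceptor angle, degrees.
#' @param tail_window Optional fraction in (0, 1]; only the final
#'   `round(tail_window * n_frames)` frames are analysed.
#' @return Tibble `frame, count` with attribute `n_frames_used`.
#' @export
count_hbonds <- function(traj, d_max = 3.5, angle_min = 150,
                         tail_window = NULL) {
  at <- traj$atoms
  abort_if(!all(unique(at$resname) %in% names(WC_DONORS)),
           paste0("unknown residue type(s): ",
                  paste(setdiff(unique(at$resname), names(WC_DONORS)),
                        collapse = ", ")))
  res_key <- paste(at$chain, at$resid)
  is_donor <- purrr::map_lgl(seq_len(nrow(at)),
                             ~at$name[.x] %in% WC_DONORS[[at$resname[.x]]])
  is_acceptor <- purrr::map_lgl(seq_len(nrow(at)),
                                ~at$name[.x] %in% WC_ACCEPTORS[[at$resname[.x]]])
  don <- which(is_donor)
  acc <- which(is_acceptor)
  anchor <- purrr::map_int(don, function(i) {
    j <- which(res_key == res_key[i] & at$name == "C1'")
    abort_if(length(j) == 0L, "donor residue lacks its C1' anchor")
    j[1L]
  })
  # cross-strand donor/acceptor pair index
  pair_ok <- outer(at$chain[don], at$chain[acc], `!=`)

  frames_all <- seq_len(n_frames(traj))
  if (!is.null(tail_window)) {
    abort_if(tail_window <= 0 || tail_window > 1,
             "`tail_window` must be in (0, 1]")
    n_used <- max(1L, round(tail_window * length(frames_all)))
    frames_all <- utils::tail(frames_all, n_used)
  }

  cos_min <- cos(angle_min * pi / 180)
  counts <- purrr::map_int(frames_all, function(f) {
    xyz <- frame_coords(traj, f)
    dpos <- xyz[don, , drop = FALSE]
    apos <- xyz[acc, , drop = FALSE]
    anch <- xyz[anchor, , drop = FALSE]
    n_hb <- 0L
    for (k in seq_along(don)) {
      dv <- sweep(apos, 2L, dpos[k, ])            # donor -> acceptor
      dist <- sqrt(rowSums(dv^2))
      ok <- pair_ok[k, ] & dist <= d_max & dist > 1e-9
      if (!any(ok)) next
      av <- anch[k, ] - dpos[k, ]                  # donor -> anchor
      av <- av / vnorm(av)
      cosang <- (dv[ok, , drop = FALSE] %*% av) / dist[ok]
      # angle(anchor, donor, acceptor) >= angle_min  <=>  cos <= cos_min
      n_hb <- n_hb + sum(cosang <= cos_min)
    }
    n_hb
  })
  out <- tibble::tibble(frame = frames_all, count = counts)
  attr(out, "n_frames_used") <- length(frames_all)
  out
}
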