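# Idealized B-DNA fixture geometry.
#
# Coarse per-residue representation: phosphate P, sugar C1' and the
# Watson-Crick donor/acceptor atoms of the base edge, laid out in each
# base-pair frame (x toward the major groove, y along Watson C1' -> Crick
# C1', z the helical advance).  The geometry is an idealization chosen so
# that cross-strand P-P distances and H-bond counts behave like fiber B-DNA;
# it makes no claim of atomistic realism.

C1_HALF_SEP <- 5.2      # half the C1'-C1' separation, angstrom
P_RADIUS <- 9.4         # phosphate distance from the axis, angstrom
P_AZIMUTH_DEG <- 108.5  # phosphate azimuth from +x, Watson at -, Crick at +
EDGE_Y <- 1.45          # half the donor-acceptor H-bond distance, angstrom

# Watson-Crick hydrogen-bond atom pairs, listed purine-first, with the
# lateral slot position (angstrom along the base long axis) of each bond.
wc_bond_table <- function(purine) {
  switch(purine,
    A = tibble::tibble(pu = c("N6", "N1"), py = c("O4", "N3"),
                       slot = c(-1.1, 1.1)),
    G = tibble::tibble(pu = c("O6", "N1", "N2"), py = c("N4", "N3", "O2"),
                       slot = c(-2.05, 0, 2.05)),
    stop("internal: purine must be A or G")
  )
}

# donor / acceptor identity of WC edge atoms, by base
WC_DONORS <- list(DA = "N6", DT = "N3", DG = c("N1", "N2"), DC = "N4")
WC_ACCEPTORS <- list(DA = "N1", DT = "O4", DG = "O6", DC = c("N3", "O2"))

residue_local_atoms <- function(base, partner, is_watson) {
  s <- if (is_watson) -1 else 1   # which side of the bp long axis (y)
  purine <- if (base %in% c("A", "G")) base else partner
  bonds <- wc_bond_table(purine)
  own <- if (base %in% c("A", "G")) bonds$pu else bonds$py
  tibble::tibble(
    name = c("P", "C1'", own),
    x = c(P_RADIUS * cospi(P_AZIMUTH_DEG / 180), 0, bonds$slot),
    y = c(P_RADIUS * sinpi(s * P_AZIMUTH_DEG / 180),
          s * C1_HALF_SEP, rep(s * EDGE_Y, nrow(bonds))),
    z = 0
  )
}

#' Simulate an idealized B-DNA duplex trajectory
#'
#' Builds a coarse duplex (P, C1' and Watson-Crick donor/acceptor atoms per
#' residue) on a straight helical axis with the given twist and rise.  The
#' complementary strand is generated by Watson-Crick pairing, antiparallel.
#' Optional Gaussian positional jitter produces fluctuating frames, and a
#' finite `bend_radius` maps the straight axis onto a circular arc for
#' curvature tests.
#'
#' @param sequence Watson-strand sequence over A, C, G, T (length >= 4).
#' @param twist_deg Helical twist per step, degrees.
#' @param rise_A Helical rise per step, angstrom.
#' @param n_frames Number of frames.
#' @param jitter_sd Per-coordinate Gaussian jitter sd, angstrom.
#' @param bend_radius Radius (angstrom) of the circular arc onto which the
#'   axis is bent; `Inf` keeps the axis straight.
#' @param seed Integer seed for the jitter, or NULL.
#' @return A [dna_trajectory()] with a Watson chain "A" (resid 1..n, 5'->3')
#'   and a Crick chain "B" (resid 1..n, 5'->3', so level i pairs with Crick
#'   resid n+1-i); the pairing table is attached.
#' @examples
#' traj <- simulate_ideal_duplex("TATGTATATTTTGTAATTAA")
#' traj
#' @export
simulate_ideal_duplex <- function(sequence, twist_deg = 36, rise_A = 3.38,
                                  n_frames = 1L, jitter_sd = 0,
                                  bend_radius = Inf, seed = NULL) {
  bases <- check_dna_sequence(sequence)
  n <- length(bases)
  abort_if(n < 4L, "`sequence` must have length >= 4")
  abort_if(n_frames < 1L, "`n_frames` must be >= 1")
  comp <- unname(complement_base(bases))

  build_residue <- function(level, base, partner, is_watson) {
    loc <- residue_local_atoms(base, partner, is_watson)
    theta <- (level - 1) * twist_deg * pi / 180
    ct <- cos(theta); st <- sin(theta)
    tibble::tibble(
      level = level,
      name = loc$name,
      resname = paste0("D", base),
      chain = if (is_watson) "A" else "B",
      resid = if (is_watson) level else n + 1L - level,
      x = ct * loc$x - st * loc$y,
      y = st * loc$x + ct * loc$y,
      z = (level - 1) * rise_A
    )
  }

  rows <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n), ~build_residue(.x, bases[.x], comp[.x], TRUE)),
    purrr::map_dfr(seq_len(n), ~build_residue(.x, comp[.x], bases[.x], FALSE))
  )
  rows <- dplyr::arrange(rows, .data$chain, .data$resid, .data$name)

  xyz <- as.matrix(rows[, c("x", "y", "z")])
  if (is.finite(bend_radius)) {
    abort_if(bend_radius <= 0, "`bend_radius` must be positive")
    alpha <- xyz[, 3L] / bend_radius
    r <- bend_radius + xyz[, 1L]
    xyz <- cbind(r * cos(alpha) - bend_radius, xyz[, 2L], r * sin(alpha))
  }

  na_ <- nrow(rows)
  coords <- array(0, dim = c(n_frames, na_, 3L))
  jit <- with_seed_(seed, {
    if (jitter_sd > 0) {
      array(stats::rnorm(n_frames * na_ * 3L, 0, jitter_sd),
            dim = c(n_frames, na_, 3L))
    } else {
      array(0, dim = c(n_frames, na_, 3L))
    }
  })
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz + jit[f, , ]

  atoms <- tibble::tibble(
    serial = seq_len(na_),
    name = rows$name,
    resname = rows$resname,
    chain = rows$chain,
    resid = rows$resid,
    element = substr(rows$name, 1L, 1L)
  )
  pairing <- tibble::tibble(
    level = seq_len(n),
    watson_chain = "A", watson_resid = seq_len(n),
    crick_chain = "B", crick_resid = n:1
  )
  dna_trajectory(atoms, coords, pairing = pairing,
                 metadata = list(sequence = paste(bases, collapse = ""),
                                 twist_deg = twist_deg, rise_A = rise_A,
                                 jitter_sd = jitter_sd,
                                 bend_radius = bend_radius))
}

#' Sequences of the duplexes studied in the melting experiments
#'
#' Watson strands of the AT-rich 20-mer (10% GC), the GC-rich 20-mer
#' (80% GC) and the two 12-mers used in the multi-duplex condensation
#' systems.
#'
#' @return Tibble with columns `id`, `sequence`, `gc_fraction`.
#' @export
study_sequences <- function() {
  tibble::tibble(
    id = c("seq1_at_rich", "seq2_gc_rich", "at_rich_12mer", "gc_rich_12mer"),
    sequence = c("TATGTATATTTTGTAATTAA", "GTCCACGCCCGGTGCGACGG",
                 "TGTATATTTTGT", "CACGCCCGGTGC")
  ) |>
    dplyr::mutate(gc_fraction = purrr::map_dbl(.data$sequence, gc_content))
}
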