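# Shared fixtures, built once per test run.

SEQ1_AT <- "TATGTATATTTTGTAATTAA"
SEQ2_GC <- "GTCCACGCCCGGTGCGACGG"
PAPER_CTS <- c(1, 5, 20, 57) * 1e-6

ideal_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      traj <- simulate_ideal_duplex(SEQ1_AT)
      fr <- compute_bp_frames(traj)
      cache <<- list(traj = traj, frames = fr, axis = axis_from_frames(fr))
    }
    cache
  }
})

# noiseless Tm table at the four experimental strand concentrations
tm_table_for <- function(dH, dS, cts = PAPER_CTS, noise_sd = 0, seed = NULL,
                         t_grid = seq(310, 375, by = 0.25)) {
  tms <- purrr::map_dbl(seq_along(cts), function(i) {
    find_tm(simulate_melting_curve(dH, dS, cts[i], t_grid = t_grid,
                                   noise_sd = noise_sd,
                                   seed = if (is.null(seed)) NULL else seed + i))
  })
  tibble::tibble(ct_M = cts, tm_K = tms)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

# apply a rigid-body motion to every frame of a trajectory
transform_trajectory <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  for (f in seq_len(n_frames(traj))) {
    traj$coords[f, , ] <- frame_coords(traj, f) %*% t(R) +
      matrix(shift, n_atoms(traj), 3, byrow = TRUE)
  }
  traj
}
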