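test_that("step parameters are exact on the ideal fixture and rigid-motion invariant", {
  fx <- ideal_fixture()
  hp <- helpar_extract(fx$frames, which = "step")
  expect_equal(hp$value[hp$parameter == "twist"], rep(36, 19),
               tolerance = 1e-9)
  expect_equal(hp$value[hp$parameter == "rise"], rep(3.38, 19),
               tolerance = 1e-9)

  moved <- transform_trajectory(fx$traj, random_rotation(21), c(13, -7, 40))
  hp2 <- helpar_extract(compute_bp_frames(moved), which = "step")
  expect_lt(max(abs(hp2$value - hp$value)), 1e-8)
})

test_that("intra-base-pair parameters vanish on ideal geometry and move under perturbation", {
  fx <- ideal_fixture()
  hp <- helpar_extract(fx$frames, which = "intra")
  expect_lt(max(abs(hp$value)), 1e-6)

  # displace one Watson base rigidly in the base-pair plane: the in-plane
  # translational parameters (shear/stretch) pick up the full 0.5 A
  traj <- simulate_ideal_duplex("ACGTACGT")
  idx <- select_atoms(traj, chain = "A", resid = 4)
  edge <- idx[traj$atoms$name[idx] %in% c("N6", "N1", "O4", "N3", "C1'")]
  traj$coords[1, edge, 2] <- traj$coords[1, edge, 2] - 0.5
  hp2 <- helpar_extract(compute_bp_frames(traj), which = "intra")
  u4 <- hp2[hp2$unit == 4, ]
  inplane <- sqrt(sum(u4$value[u4$parameter %in% c("shear", "stretch")]^2))
  expect_equal(inplane, 0.5, tolerance = 1e-6)
  expect_equal(u4$value[u4$parameter == "stagger"], 0, tolerance = 1e-9)
})

test_that("mid-frame decomposition round-trips its own reconstruction", {
  mfp <- groovetherm:::mid_frame_params
  mfr <- groovetherm:::mid_frame_reconstruct
  withr::with_seed(42, {
    for (i in 1:25) {
      T1 <- random_rotation(i)
      o1 <- stats::rnorm(3)
      p <- c(stats::rnorm(3), stats::runif(1, -8, 8), stats::runif(1, -10, 10),
             stats::runif(1, 20, 40))
      r <- mfr(o1, T1, p)
      expect_equal(mfp(o1, T1, r$o, r$T), p, tolerance = 1e-10)
    }
  })
})

test_that("KL divergence is zero on identity, matches the Gaussian closed form, and regularizes", {
  withr::with_seed(1, {
    a <- stats::rnorm(5e4)
    b <- stats::rnorm(5e4, 1)
    c_ <- stats::runif(500, 10, 11)
  })
  expect_lt(kl_divergence(a, a), 1e-12)
  expect_equal(kl_divergence(a, b), 0.5, tolerance = 0.05 / 0.5)
  disjoint <- kl_divergence(a, c_)
  expect_true(is.finite(disjoint) && disjoint > 5)
  expect_error(kl_divergence(a[1:10], b), "100 samples")
})

test_that("stiffness recovery: 1-D exact relation, matrix recovery, temperature linearity", {
  sim1 <- simulate_helpar(matrix(9.977), n_frames = 5e4, seed = 10)
  st1 <- stiffness_from_covariance(sim1)
  k1 <- attr(st1, "matrices")[["1"]][1, 1]
  expect_equal(k1, 9.977, tolerance = 4 * sqrt(2 / 5e4))

  K <- matrix(0.3, 6, 6)
  diag(K) <- c(6, 9, 14, 0.045, 0.03, 0.06) * 10
  sim <- simulate_helpar(K, n_frames = 3e4, seed = 11)
  Khat <- attr(stiffness_from_covariance(sim), "matrices")[["1"]]
  expect_lt(norm(Khat - K, "F") / norm(K, "F"), 0.05)

  st_hot <- stiffness_from_covariance(sim1, temperature = 600)
  expect_equal(attr(st_hot, "matrices")[["1"]][1, 1], 2 * k1,
               tolerance = 1e-12)
})

test_that("singular covariance falls back to a flagged pseudo-inverse", {
  base <- simulate_helpar(diag(2), n_frames = 200, seed = 12,
                          parameters = c("a", "b"))
  dup <- base[base$parameter == "a", ]
  dup$parameter <- "b"
  degen <- dplyr::bind_rows(base[base$parameter == "a", ], dup)
  expect_warning(st <- stiffness_from_covariance(degen), "pseudo-inverse")
  expect_true(attr(st, "degenerate")[["1"]])
})

test_that("overall stiffness averages diagonals with the stated conventions", {
  mk_series <- function(diags, n = 200) {
    purrr::imap_dfr(diags, function(d, i) {
      simulate_helpar(diag(d), n_frames = n, seed = i,
                      parameters = c("shift", "slide", "rise", "tilt",
                                     "roll", "twist"),
                      unit = i)
    })
  }
  # exactly-known diagonals, bypassing sampling: build the result directly
  fake <- stiffness_from_covariance(
    mk_series(list(rep(1, 6), rep(1, 6))), temperature = 300
  )
  m <- attr(fake, "matrices")
  m[["1"]] <- diag(6); m[["2"]] <- diag(6)
  dimnames(m[["1"]]) <- dimnames(m[["2"]]) <-
    list(c("shift", "slide", "rise", "tilt", "roll", "twist"),
         c("shift", "slide", "rise", "tilt", "roll", "twist"))
  rebuilt <- fake
  rebuilt$k <- c(as.vector(m[["1"]]), as.vector(m[["2"]]))
  ov <- overall_stiffness(rebuilt)
  expect_equal(ov$per_step$combined_mean, c(1, 1))
  expect_equal(unname(ov$molecule["combined_mean"]), 1)

  rebuilt2 <- rebuilt
  rebuilt2$k[rebuilt2$unit == 1 & rebuilt2$par_row == rebuilt2$par_col] <- 2
  rebuilt2$k[rebuilt2$unit == 2 & rebuilt2$par_row == rebuilt2$par_col] <- 4
  ov2 <- overall_stiffness(rebuilt2)
  expect_equal(unname(ov2$molecule["combined_mean"]), 3)

  # doubling K doubles the molecule scalar
  rebuilt3 <- rebuilt2
  rebuilt3$k <- 2 * rebuilt3$k
  expect_equal(unname(overall_stiffness(rebuilt3)$molecule["combined_mean"]),
               6)
})

test_that("essential dynamics recovers supplied and sampled covariances", {
  e <- ed_eigen_from_cov(diag(c(4, 1, rep(0, 8))))
  expect_equal(e$values[1:2], c(4, 1))
  expect_equal(e$sum_first_k, 5)
  expect_equal(sum(e$values), e$trace, tolerance = 1e-8)

  # identical inputs give a zero eigenvalue-sum difference
  withr::with_seed(3, X <- matrix(stats::rnorm(600), 50, 12))
  ea <- ed_eigen(X, superpose = FALSE)
  expect_equal(ed_sum_diff(ea, ea), 0)

  # generator with known covariance: sum of first 10 vs analytic partial trace
  K <- diag(seq(0.5, 6, length.out = 12))
  Ctrue <- kBT_kJ(300) * solve(K)
  sim <- simulate_helpar(K, n_frames = 4e4, seed = 13,
                         parameters = sprintf("p%02d", 1:12))
  W <- helpar_wide(sim)
  ev <- ed_eigen(W, superpose = FALSE)
  partial <- sum(sort(diag(Ctrue), decreasing = TRUE)[1:10])
  expect_equal(ev$sum_first_k, partial, tolerance = 0.05)
  expect_error(ed_eigen(W[1:8, ]), "k \\+ 1")
})

test_that("superposed essential dynamics removes rigid-body motion", {
  traj <- simulate_ideal_duplex("ACGTACGTAC", n_frames = 30, jitter_sd = 0.05,
                                seed = 14)
  spun <- traj
  for (f in seq_len(30)) {
    R <- rotation_matrix <- groovetherm:::rotation_matrix(c(0, 0, 1),
                                                          f * 0.2)
    spun$coords[f, , ] <- frame_coords(traj, f) %*% t(R)
  }
  e_plain <- ed_eigen(traj, k = 10)
  e_spun <- ed_eigen(spun, k = 10)
  expect_equal(e_spun$sum_first_k, e_plain$sum_first_k, tolerance = 0.2)
})

test_that("covariance overlap matches the brute-force double loop", {
  expect_equal(covariance_overlap(diag(c(3, 2, 1)), diag(c(3, 2, 1)), k = 3), 1)
  A <- diag(c(1, 1, 0, 0)); B <- diag(c(0, 0, 1, 1))
  expect_equal(covariance_overlap(A, B, k = 2), 0)

  withr::with_seed(4, {
    for (i in 1:5) {
      Q1 <- random_rotation(100 + i)
      d <- 3
      C1 <- Q1 %*% diag(c(5, 2, 1)) %*% t(Q1)
      Q2 <- random_rotation(200 + i)
      C2 <- Q2 %*% diag(c(4, 3, 0.5)) %*% t(Q2)
      k <- 2
      v <- eigen(C1, symmetric = TRUE)$vectors
      w <- eigen(C2, symmetric = TRUE)$vectors
      brute <- 0
      for (a in 1:k) for (b in 1:k) brute <- brute + sum(v[, a] * w[, b])^2
      expect_equal(covariance_overlap(C1, C2, k = k), brute / k,
                   tolerance = 1e-12)
      expect_equal(covariance_overlap(C1, C2, k = k),
                   covariance_overlap(C2, C1, k = k), tolerance = 1e-12)
    }
  })
  expect_error(covariance_overlap(diag(3), diag(4)), "dimension")
})

test_that("H-bond counting reproduces the sequence-determined totals", {
  fx <- ideal_fixture()
  hb <- count_hbonds(fx$traj)
  expect_identical(hb$count, 42L)  # 18 AT pairs x 2 + 2 GC pairs x 3

  gc <- count_hbonds(simulate_ideal_duplex(SEQ2_GC))
  expect_identical(gc$count, 56L)  # 4 x 2 + 16 x 3

  apart <- fx$traj
  bidx <- select_atoms(apart, chain = "B")
  apart$coords[1, bidx, 1] <- apart$coords[1, bidx, 1] + 20
  expect_identical(count_hbonds(apart)$count, 0L)

  multi <- simulate_ideal_duplex("ACGTACGT", n_frames = 10)
  tail4 <- count_hbonds(multi, tail_window = 0.4)
  expect_identical(attr(tail4, "n_frames_used"), 4L)
  expect_identical(tail4$frame, 7:10)

  alien <- fx$traj
  alien$atoms$resname[1] <- "XYZ"
  expect_error(count_hbonds(alien), "unknown residue")
})

test_that("groove widths are deterministic, scale with coordinates, and ignore rigid motion", {
  fx <- ideal_fixture()
  multi <- simulate_ideal_duplex(SEQ1_AT, n_frames = 3)
  gw <- groove_widths(multi)
  by_level <- tidyr::pivot_wider(gw, id_cols = "level",
                                 names_from = "frame",
                                 values_from = "minor_width")
  expect_lt(max(abs(by_level$`1` - by_level$`3`), na.rm = TRUE), 1e-6)

  gw1 <- groove_widths(fx$traj)
  ok <- !is.na(gw1$minor_width)
  expect_true(all(gw1$minor_width[ok] > 0))

  shrunk <- fx$traj
  shrunk$coords <- fx$traj$coords * 0.95
  gws <- groove_widths(shrunk)
  raw <- gw1$minor_width[ok] + 5.8
  expect_equal(gws$minor_width[ok], 0.95 * raw - 5.8, tolerance = 1e-9)

  moved <- transform_trajectory(fx$traj, random_rotation(31), c(5, 5, -9))
  gwm <- groove_widths(moved)
  expect_equal(gwm$minor_width[ok], gw1$minor_width[ok], tolerance = 1e-9)
  expect_equal(gwm$major_width[!is.na(gwm$major_width)],
               gw1$major_width[!is.na(gw1$major_width)], tolerance = 1e-9)
})
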