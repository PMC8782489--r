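test_that("base-pair triads are orthonormal right-handed with the constructed spacing", {
  fx <- ideal_fixture()
  for (i in c(1, 7, 20)) {
    Tm <- cbind(c(fx$frames$xx[i], fx$frames$xy[i], fx$frames$xz[i]),
                c(fx$frames$yx[i], fx$frames$yy[i], fx$frames$yz[i]),
                c(fx$frames$zx[i], fx$frames$zy[i], fx$frames$zz[i]))
    expect_lt(max(abs(crossprod(Tm) - diag(3))), 1e-6)
    expect_equal(det(Tm), 1, tolerance = 1e-9)
  }
  origins <- as.matrix(fx$frames[, c("ox", "oy", "oz")])
  d <- sqrt(rowSums(diff(origins)^2))
  expect_equal(d, rep(3.38, 19), tolerance = 1e-9)
  expect_equal(diff(origins[, 3]), rep(3.38, 19), tolerance = 1e-9)
})

test_that("missing atoms are reported with the offending residue", {
  traj <- simulate_ideal_duplex("ACGTAC")
  keep <- !(traj$atoms$chain == "A" & traj$atoms$resid == 3 &
              traj$atoms$name == "C1'")
  broken <- subset_trajectory(traj, which(keep))
  broken$pairing <- traj$pairing
  expect_error(compute_bp_frames(broken), "C1' in residue A:3")
})

test_that("axis fitting reproduces straight and gently curved axes", {
  fx <- ideal_fixture()
  ax <- fit_helical_axis(fx$frames)
  expect_lt(max(abs(as.matrix(ax[, c("x", "y")]))), 1e-3)
  expect_equal(ax$tz, rep(1, 20), tolerance = 1e-6)
  expect_true(all(diff(ax$arclength) > 0))

  bent <- simulate_ideal_duplex(SEQ1_AT, bend_radius = 100)
  axb <- fit_helical_axis(compute_bp_frames(bent))
  pts <- as.matrix(axb[, c("x", "y", "z")])
  # discrete curvature at interior points vs the generating arc (1/100)
  kappa <- vapply(5:16, function(i) {
    v1 <- pts[i, ] - pts[i - 3, ]
    v2 <- pts[i + 3, ] - pts[i, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    ang / ((sqrt(sum(v1^2)) + sqrt(sum(v2^2))) / 2)
  }, numeric(1))
  expect_equal(mean(kappa), 1 / 100, tolerance = 0.1)

  short <- fx$frames[fx$frames$level <= 3, ]
  expect_error(fit_helical_axis(short), "at least 4")
})

test_that("helicoidal mapping round-trips placements on a straight axis", {
  fx <- ideal_fixture()
  set.seed(11)
  D <- runif(50, 2, 60); R <- runif(50, 0.5, 19); A <- runif(50, 0, 359.9)
  pos <- place_helicoidal(fx$axis, fx$frames, D, R, A)
  hc <- to_helicoidal(fx$axis, fx$frames, pos)
  expect_equal(hc$D, D, tolerance = 1e-9)
  expect_equal(hc$R, R, tolerance = 1e-9)
  expect_equal(hc$A, A, tolerance = 1e-9)

  # on-axis sentinel
  onax <- to_helicoidal(fx$axis, fx$frames, matrix(c(0, 0, 10), 1))
  expect_equal(onax$R, 0)
  expect_equal(onax$A, 0)
})

test_that("round trip survives a gently bent axis within 0.1 A / 1 deg", {
  bent <- simulate_ideal_duplex(SEQ1_AT, bend_radius = 150)
  fr <- compute_bp_frames(bent)
  ax <- axis_from_frames(fr)
  set.seed(12)
  D <- runif(20, 5, 58); R <- runif(20, 1, 15); A <- runif(20, 5, 350)
  pos <- place_helicoidal(ax, fr, D, R, A)
  hc <- to_helicoidal(ax, fr, pos)
  expect_lt(max(abs(hc$R - R)), 0.1)
  expect_lt(max(pmin(abs(hc$A - A), 360 - abs(hc$A - A))), 1)
})

test_that("groove probes calibrate the azimuth origin at every level", {
  fx <- ideal_fixture()
  for (i in seq_len(20)) {
    r <- fx$frames[i, ]
    o <- c(r$ox, r$oy, r$oz); xv <- c(r$xx, r$xy, r$xz)
    minor <- to_helicoidal(fx$axis, fx$frames, matrix(o - 4 * xv, 1))$A
    major <- to_helicoidal(fx$axis, fx$frames, matrix(o + 4 * xv, 1))$A
    expect_true(minor >= 33 && minor < 147)
    expect_false(major >= 33 && major < 147)
  }
})

test_that("region assignment honours the half-open groove and radial boundaries", {
  spec <- region_spec()
  mk <- function(D, R, A) {
    h <- tibble::tibble(D = D, R = R, A = A)
    attr(h, "d_span") <- c(0, 64)
    as.character(assign_region(h, spec)$region)
  }
  expect_identical(mk(10, 8, 90), "minor_inner")
  expect_identical(mk(10, 15, 200), "major_outer")
  expect_identical(mk(10, 25, 90), "bulk")
  # half-open angle window and closed radial boundaries
  expect_identical(mk(10, 8, 33), "minor_inner")
  expect_identical(mk(10, 8, 147), "major_inner")
  expect_identical(mk(10, 10.25, 90), "minor_inner")
  expect_identical(mk(10, 20.5, 90), "minor_outer")
  expect_identical(mk(-1, 8, 90), "bulk")   # outside the duplex span
  expect_identical(mk(65, 8, 90), "bulk")
})

test_that("region labels partition every particle exactly once", {
  fx <- ideal_fixture()
  cl <- simulate_ion_cloud(fx$axis, fx$frames,
                           region_molarity = c(minor_inner = 1, major_outer = 1),
                           bulk_molarity = 0.3, box = c(100, 100, 120),
                           n_frames = 10, seed = 3)
  hc <- assign_region(map_particles(cl, fx$axis, fx$frames))
  expect_false(anyNA(hc$region))
  expect_identical(sum(table(hc$region)), nrow(hc))
})

test_that("density map converts counts to molarity exactly", {
  # one ion always in one 1 nm^3 cell: molarity = 1/(N_A * 1e-24 L)
  h <- tibble::tibble(frame = 1:50, D = 5, R = 2.5, A = 45)
  attr(h, "d_span") <- c(0, 10)
  # cell: R in [0,5] (R_mid 2.5), A in [0,90]: V = 10 * 2.5 * 5 * pi/2
  dm <- density_map(h, r_breaks = c(0, 5), a_breaks = c(0, 90, 180, 270, 360))
  cell <- dm[dm$a_lo == 0, ]
  v <- 10 * 2.5 * 5 * (pi / 2)
  expect_equal(cell$mean_count, 1)
  expect_equal(cell$molarity, 1 / (6.02214076e23 * v * 1e-27),
               tolerance = 1e-12)
  expect_equal(dm$molarity[dm$a_lo == 90], 0)

  # a cell of exactly 1 nm^3: dD=100, r in [4,6] (r_mid 5, dr 2), dA=1 rad
  scaled <- tibble::tibble(frame = 1, D = 50, R = 5, A = 28)
  one_nm3 <- density_map(scaled, r_breaks = c(4, 6),
                         a_breaks = c(0, 180 / pi), d_span = c(0, 100))
  expect_equal(one_nm3$cell_volume[1], 1000, tolerance = 1e-9)
  expect_equal(one_nm3$molarity[1], 1.661, tolerance = 1e-3)
})

test_that("density conservation: cell molarities integrate back to the mean count", {
  fx <- ideal_fixture()
  cl <- simulate_ion_cloud(fx$axis, fx$frames,
                           region_molarity = c(minor_inner = 1, minor_outer = 2,
                                               major_inner = 0.5, major_outer = 1),
                           n_frames = 25, seed = 4)
  h <- map_particles(cl, fx$axis, fx$frames)
  dm <- density_map(h, n_frames = 25)
  NA_ <- 6.02214076e23
  integrated <- sum(dm$molarity * dm$cell_volume) * 1e-27 * NA_
  d_span <- attr(h, "d_span")
  in_grid <- h$R <= 20.5 & h$D >= d_span[1] & h$D <= d_span[2]
  expect_equal(integrated, sum(in_grid) / 25, tolerance = 1e-6)
})

test_that("uniform clouds give bulk ratios near one and loaded grooves recover their enrichment", {
  fx <- ideal_fixture()
  m <- 0.8
  cl <- simulate_ion_cloud(fx$axis, fx$frames,
                           region_molarity = c(minor_inner = m, major_inner = m,
                                               minor_outer = m, major_outer = m),
                           bulk_molarity = m, box = c(110, 110, 160),
                           n_frames = 150, seed = 5)
  h <- map_particles(cl, fx$axis, fx$frames)
  dm <- bulk_ratio(density_map(h, box_volume = 110 * 110 * 160,
                               n_frames = 150))
  overall <- sum(dm$molarity * dm$cell_volume) / sum(dm$cell_volume) /
    attr(dm, "bulk_molarity")
  expect_equal(overall, 1, tolerance = 0.05)

  enriched <- simulate_ion_cloud(fx$axis, fx$frames,
                                 region_molarity = c(minor_inner = 50 * 0.02),
                                 bulk_molarity = 0.02,
                                 box = c(110, 110, 160),
                                 n_frames = 300, seed = 6)
  he <- assign_region(map_particles(enriched, fx$axis, fx$frames))
  n_minor <- sum(he$region == "minor_inner") / 300
  v_minor <- diff(attr(he, "d_span")) * (114 * pi / 180) / 2 * 10.25^2
  ratio <- (n_minor / (6.02214076e23 * v_minor * 1e-27)) / 0.02
  expect_equal(ratio, 50, tolerance = 3 / sqrt(sum(he$region == "minor_inner")) * 3)

  empty <- density_map(tibble::tibble(frame = 1, D = 2, R = 1, A = 10),
                       d_span = c(0, 10))
  expect_error(bulk_ratio(empty), "bulk molarity")
})

test_that("occupancy convergence tracks stationary and drifting generators", {
  fx <- ideal_fixture()
  cl <- simulate_ion_cloud(fx$axis, fx$frames,
                           region_molarity = c(minor_inner = 1.2),
                           n_frames = 200, seed = 7)
  h <- assign_region(map_particles(cl, fx$axis, fx$frames))
  cv <- convergence_series(h, "minor_inner")
  lambda <- 1.2 * 6.02214076e23 *
    (diff(attr(h, "d_span")) * (114 * pi / 180) / 2 * 10.25^2) * 1e-27
  final <- utils::tail(cv$series$running_mean, 1)
  expect_equal(final, lambda, tolerance = 3 * sqrt(lambda / 200) / lambda)
  expect_false(cv$drift_flag)

  # constant occupancy: flat running mean at 2
  const <- tibble::tibble(frame = rep(1:20, each = 2), D = 5, R = 5, A = 90)
  attr(const, "d_span") <- c(0, 64)
  constr <- assign_region(const)
  cv2 <- convergence_series(constr, "minor_inner")
  expect_equal(cv2$series$running_mean, rep(2, 20))
  expect_false(cv2$drift_flag)

  # linear drift in occupancy trips the flag
  drift <- tibble::tibble(frame = rep(1:50, times = 1:50), D = 5, R = 5,
                          A = 90)
  driftr <- assign_region(drift, d_span = c(0, 64))
  expect_true(convergence_series(driftr, "minor_inner")$drift_flag)
  expect_error(convergence_series(constr[constr$frame <= 5, ], "minor_inner"),
               "10 frames")
})

test_that("radial profiles are flat for uniform clouds and peaked for rings", {
  fx <- ideal_fixture()
  m <- 1
  cl <- simulate_ion_cloud(fx$axis, fx$frames,
                           region_molarity = c(minor_inner = m, major_inner = m),
                           n_frames = 200, seed = 8)
  h <- map_particles(cl, fx$axis, fx$frames)
  rd <- radial_distribution(h, dr = 2.05)
  expect_equal(mean(rd$molarity[rd$r_lo >= 2]), m, tolerance = 0.1)

  ring <- tibble::tibble(frame = rep(1:10, each = 20),
                         D = rep(seq(2, 60, length.out = 20), 10),
                         R = 8.5, A = 90)
  attr(ring, "d_span") <- c(0, 64.22)
  rr <- radial_distribution(ring, dr = 1)
  expect_identical(rr$r_lo[rr$groove == "minor"][which.max(
    rr$molarity[rr$groove == "minor"])], 8)
  expect_true(all(rr$molarity[rr$groove == "major"] == 0))

  none <- tibble::tibble(frame = 1, D = 2, R = 30, A = 90)
  attr(none, "d_span") <- c(0, 64.22)
  expect_true(all(radial_distribution(none, dr = 1)$molarity == 0))
  expect_error(radial_distribution(ring, dr = 0), "positive")
})
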