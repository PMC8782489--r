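test_that("two-state generator puts the derivative maximum at the closed-form Tm", {
  expect_equal(tm_two_state(-100, -0.270, 2.5e-6), 336.688, tolerance = 1e-4)
  crv <- simulate_melting_curve(-100, -0.270, 2.5e-6,
                                t_grid = seq(300, 370, 0.25))
  expect_equal(find_tm(crv), tm_two_state(-100, -0.270, 2.5e-6),
               tolerance = 0.2 / 336)
})

test_that("noiseless curves with flat baselines are monotone and seed-reproducible", {
  tg <- seq(300, 370, 0.5)
  crv <- simulate_melting_curve(-100, -0.270, 2.5e-6, t_grid = tg)
  expect_true(all(diff(crv$absorbance) >= 0))
  a <- simulate_melting_curve(-100, -0.270, 2.5e-6, t_grid = tg,
                              noise_sd = 0.01, seed = 7)
  b <- simulate_melting_curve(-100, -0.270, 2.5e-6, t_grid = tg,
                              noise_sd = 0.01, seed = 7)
  expect_identical(a$absorbance, b$absorbance)
})

test_that("generator rejects invalid model specifications", {
  expect_error(simulate_melting_curve(100, -0.27, 1e-6), "negative")
  expect_error(simulate_melting_curve(-100, -0.27, -1e-6), "positive")
  expect_error(simulate_melting_curve(-100, -0.27, 1e-6,
                                      t_grid = c(300, 299, 301, 302, 303, 304, 305)),
               "increasing")
})

test_that("shrinking-window smoother preserves low-order polynomials and matches sgolayfilt inside", {
  tg <- seq(300, 340, length.out = 81)
  const <- tibble::tibble(temperature_K = tg, absorbance = rep(2, 81))
  expect_equal(smooth_curve(const)$absorbance, const$absorbance)

  poly <- tibble::tibble(temperature_K = tg,
                         absorbance = 1 + 0.02 * tg - 3e-4 * tg^2 + 1e-6 * tg^3)
  expect_equal(smooth_curve(poly, 11, 3)$absorbance, poly$absorbance,
               tolerance = 1e-10)

  withr::with_seed(1, {
    noisy <- tibble::tibble(temperature_K = tg, absorbance = rnorm(81))
  })
  sm <- smooth_curve(noisy, 11, 3)
  expect_lt(stats::var(sm$absorbance), stats::var(noisy$absorbance))

  skip_if_not_installed("signal")
  ref <- signal::sgolayfilt(noisy$absorbance, p = 3, n = 11)
  interior <- 6:76  # away from the endpoint transients
  expect_equal(sm$absorbance[interior], ref[interior], tolerance = 1e-8)
})

test_that("smoother rejects bad window/order combinations", {
  tg <- seq(300, 310, length.out = 21)
  crv <- tibble::tibble(temperature_K = tg, absorbance = tg)
  expect_error(smooth_curve(crv, window = 10), "odd")
  expect_error(smooth_curve(crv, window = 23), "exceed")
  expect_error(smooth_curve(crv, window = 5, order = 5), "order")
})

test_that("find_tm locates a symmetric sigmoid midpoint and flags missing transitions", {
  tg <- seq(320, 365, by = 0.5)
  crv <- tibble::tibble(temperature_K = tg,
                        absorbance = 1 / (1 + exp(-(tg - 343.2) / 2)))
  expect_equal(find_tm(crv), 343.2, tolerance = 0.05 / 343)

  ramp <- tibble::tibble(temperature_K = tg, absorbance = 0.001 * tg)
  expect_error(find_tm(ramp), "transition not captured")
})

test_that("van 't Hoff fit recovers exact parameters from noiseless Tm values", {
  tms <- tm_two_state(-100, -0.270, PAPER_CTS)
  vf <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms))
  expect_equal(vf$dH_kcal, -100, tolerance = 1e-6)
  expect_equal(vf$dS_kcal, -0.270, tolerance = 1e-6)
  expect_equal(vf$r2, 1, tolerance = 1e-9)
  expect_equal(vf$dG_ref_kcal, vf$dH_kcal - 300 * vf$dS_kcal,
               tolerance = 1e-12)
  expect_identical(vf$direction, "association")
})

test_that("van 't Hoff fit needs three concentrations with spread", {
  tms <- tm_two_state(-100, -0.270, PAPER_CTS)
  expect_error(fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS[1:2],
                                            tm_K = tms[1:2])), "3 distinct")
  expect_error(fit_vant_hoff(tibble::tibble(ct_M = rep(1e-6, 4), tm_K = tms)),
               "3 distinct")
})

test_that("dH is invariant to the concentration unit, dS absorbs the intercept shift", {
  tms <- tm_two_state(-100, -0.270, PAPER_CTS)
  vf_M <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms))
  vf_uM <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS * 1e6, tm_K = tms))
  expect_equal(vf_uM$dH_kcal, vf_M$dH_kcal, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(vf_uM$dS_kcal, vf_M$dS_kcal)))
})

test_that("generator and fitter share the concentration convention (round trip at Ct/4 too)", {
  tms4 <- purrr::map_dbl(PAPER_CTS, function(ct) {
    find_tm(simulate_melting_curve(-100, -0.270, ct, conc_divisor = 4,
                                   t_grid = seq(310, 375, 0.25)))
  })
  vf4 <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms4),
                       conc_divisor = 4)
  expect_equal(vf4$dH_kcal, -100, tolerance = 1e-3)
})

test_that("delta_tm matches conditions, averages replicates and reports the gap", {
  a <- tibble::tibble(condition = c("NaP", "NaP", "ArgCl"),
                      tm_K = c(340.0, 340.4, 351))
  b <- tibble::tibble(condition = c("NaP", "ArgCl"), tm_K = c(368, 366))
  out <- delta_tm(a, b)
  nap <- out[out$condition == "NaP", ]
  expect_equal(nap$tm_mean_a, 340.2)
  expect_equal(nap$tm_sd_a, stats::sd(c(340.0, 340.4)))
  expect_equal(nap$delta_tm_K, 340.2 - 368)

  gc_at <- delta_tm(tibble::tibble(condition = "NaP", tm_K = 368),
                    tibble::tibble(condition = "NaP", tm_K = 333))
  expect_equal(gc_at$delta_tm_K, 35)
  expect_equal(delta_tm(a, a)$delta_tm_K, c(0, 0))
  expect_error(delta_tm(a, tibble::tibble(condition = "LysCl", tm_K = 1)),
               "do not match")
})

test_that("delta_tm_vs_reference anchors on the control buffer", {
  tbl <- tibble::tibble(condition = c("NaP", "ArgCl", "LysCl"),
                        tm_K = c(340, 352, 349))
  out <- delta_tm_vs_reference(tbl, "NaP")
  expect_equal(out$delta_tm_K[out$condition == "ArgCl"], 12)
  expect_equal(out$delta_tm_K[out$condition == "NaP"], 0)
  expect_error(delta_tm_vs_reference(tbl, "KCl"), "not present")
})

test_that("thermo_deltas reports melting-direction differences and checks flags", {
  tms <- tm_two_state(-100, -0.270, PAPER_CTS)
  ref <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms))
  tms2 <- tm_two_state(-105, -0.280, PAPER_CTS)
  cond <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms2))

  zero <- thermo_deltas(ref, ref)
  expect_equal(unlist(zero[, 1:3]), c(ddH_kcal = 0, ddS_kcal = 0,
                                      ddG_ref_kcal = 0), tolerance = 1e-12)

  d <- thermo_deltas(cond, ref)
  # association dH drops by 5 => melting-direction ddH = +5
  expect_equal(d$ddH_kcal, 5, tolerance = 1e-4)
  expect_equal(d$ddG_ref_kcal, d$ddH_kcal - 300 * d$ddS_kcal,
               tolerance = 1e-9)
  expect_error(thermo_deltas(flip_direction(cond), ref), "direction")
})

test_that("gc_content counts the printed sequences correctly", {
  expect_equal(gc_content(SEQ1_AT), 0.10)
  expect_equal(gc_content("GGGG"), 1.0)
  expect_equal(gc_content(SEQ2_GC), 0.80)
  expect_error(gc_content("ACGU"), "A, C, G, T")
  expect_error(gc_content(""), "")
})

test_that("tidy and glance expose the fitted thermodynamics", {
  tms <- tm_two_state(-100, -0.270, PAPER_CTS)
  vf <- fit_vant_hoff(tibble::tibble(ct_M = PAPER_CTS, tm_K = tms))
  td <- tidy(vf)
  expect_identical(td$term, c("dH", "dS", "dG300"))
  gl <- glance(vf)
  expect_equal(gl$r2, 1, tolerance = 1e-9)
  expect_identical(gl$direction, "association")
})
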