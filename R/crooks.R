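#' Simulate a Crooks-consistent bidirectional work set
#'
#' Gaussian work distributions satisfying the Crooks fluctuation theorem
#' exactly: in thermal units (k_B T) the forward works are
#' `N(dG + sigma^2/2, sigma^2)` and the reverse works
#' `N(-dG + sigma^2/2, sigma^2)`, so that
#' `P_F(W) / P_R(-W) = exp(W - dG)` in distribution.
#'
#' @param dG Free-energy difference in k_B T.
#' @param sigma Work standard deviation in k_B T (> 0).
#' @param n_forward,n_reverse Sample counts (>= 2).
#' @param temperature Temperature in kelvin (sets the k_B T to kJ/mol
#'   conversion for storage).
#' @param label Mutation-context label.
#' @param seed Integer seed or NULL.
#' @return A `work_set` tibble `direction` ("F"/"R"), `work_kJ_mol`, with
#'   attributes `temperature` and `label`.
#' @examples
#' ws <- simulate_work_set(10, sqrt(2), seed = 1)
#' crooks_intersection(ws, n_boot = 0)
#' @export
simulate_work_set <- function(dG, sigma, n_forward = 184L, n_reverse = 184L,
                              temperature = 300, label = "synthetic",
                              seed = NULL) {
  abort_if(sigma <= 0, "`sigma` must be positive")
  abort_if(n_forward < 2L || n_reverse < 2L, "need at least 2 works per direction")
  kbt <- kBT_kJ(temperature)
  with_seed_(seed, {
    wf <- stats::rnorm(n_forward, dG + sigma^2 / 2, sigma)
    wr <- stats::rnorm(n_reverse, -dG + sigma^2 / 2, sigma)
    new_work_set(
      tibble::tibble(
        direction = c(rep("F", n_forward), rep("R", n_reverse)),
        work_kJ_mol = c(wf, wr) * kbt
      ),
      temperature = temperature, label = label
    )
  })
}

new_work_set <- function(x, temperature = 300, label = "unknown") {
  class(x) <- c("work_set", class(tibble::tibble()))
  attr(x, "temperature") <- temperature
  attr(x, "label") <- label
  x
}

#' Read forward/reverse work values from CSV
#'
#' Two-column table with `direction` (F or R) and `work`; a `unit` argument
#' handles files recorded in thermal units.
#'
#' @param path CSV path.
#' @param unit `"kJ/mol"` or `"kT"`.
#' @param temperature Temperature in kelvin (used for the kT conversion and
#'   stored on the set).
#' @param label Mutation-context label.
#' @return A `work_set` tibble.
#' @export
read_work_values <- function(path, unit = c("kJ/mol", "kT"),
                             temperature = 300, label = NULL) {
  unit <- match.arg(unit)
  abort_if(!file.exists(path), paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(nrow(x) == 0L, "empty work file")
  abort_if(!all(c("direction", "work") %in% names(x)),
           "work CSV must have columns `direction` and `work`")
  dir <- toupper(trimws(as.character(x$direction)))
  bad <- setdiff(unique(dir), c("F", "R"))
  abort_if(length(bad) > 0L,
           paste0("unknown direction token(s): ", paste(bad, collapse = ", ")))
  w <- as.numeric(x$work)
  abort_if(anyNA(w), "malformed (non-numeric) work values")
  if (unit == "kT") w <- w * kBT_kJ(temperature)
  new_work_set(tibble::tibble(direction = dir, work_kJ_mol = w),
               temperature = temperature,
               label = label %||% basename(path))
}

work_split <- function(ws) {
  list(
    wf = ws$work_kJ_mol[ws$direction == "F"],
    wr = ws$work_kJ_mol[ws$direction == "R"],
    temperature = attr(ws, "temperature") %||% 300
  )
}

# Gaussian KDE evaluated at `at`, bandwidth h (Scott's rule by default).
gauss_kde <- function(samples, at, h) {
  vapply(at, function(w) mean(stats::dnorm(w, samples, h)), numeric(1))
}

scott_bw <- function(x) {
  h <- stats::bw.nrd(x)
  if (!is.finite(h) || h <= 0) h <- max(stats::sd(x), 1e-6)
  h
}

crooks_root <- function(wf, wrn, bw_scale = 1) {
  # one common bandwidth from the pooled (mean-centred) samples: with equal
  # kernels the crossing of two equal-variance densities stays at the
  # population intersection, which removes a bandwidth-asymmetry bias
  h <- scott_bw(c(wf - mean(wf), wrn - mean(wrn))) * bw_scale
  hf <- h
  hr <- h
  f <- function(w) gauss_kde(wf, w, hf) - gauss_kde(wrn, w, hr)
  lo <- min(wf, wrn); hi <- max(wf, wrn)
  grid <- seq(lo, hi, length.out = 512L)
  fv <- f(grid)
  mid <- (mean(wf) + mean(wrn)) / 2
  if (max(abs(fv)) < 1e-14) return(mid)  # degenerate: identical densities
  s <- sign(fv)
  cross <- which(s[-1L] * s[-length(s)] < 0)
  if (length(cross) == 0L) {
    # densities overlap but never cross on the grid (can happen for heavily
    # skewed resamples): fall back to the point of closest approach
    return(grid[which.min(abs(fv))])
  }
  roots <- vapply(cross, function(i) {
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                   tol = 1e-6)$root
  }, numeric(1))
  roots[which.min(abs(roots - mid))]
}

#' Crooks free energy from the work-density intersection
#'
#' Gaussian-kernel density estimates of the forward work distribution
#' `P_F(W)` and the mirrored reverse distribution `P_R(-W)` cross at
#' `W = dG` by the Crooks fluctuation theorem.  The crossing nearest the
#' midpoint of the two sample means is located by bisection to 1e-6 kJ/mol;
#' the uncertainty is a seeded bootstrap over work resamples, and a
#' bandwidth sensitivity report (x0.5, x1, x2 Scott) is attached.
#'
#' @param ws A `work_set`.
#' @param bw_scale Multiplier on the Scott's-rule bandwidth.
#' @param n_boot Bootstrap resamples for the standard error (0 skips it).
#' @param seed Seed for the bootstrap.
#' @return A `fep_estimate`: list with `dG_kJ`, `dG_kT`, `stderr_kJ`,
#'   `method = "crooks_kde"`, `n_F`, `n_R`, `temperature`, `sensitivity`.
#' @export
crooks_intersection <- function(ws, bw_scale = 1, n_boot = 200L,
                                seed = NULL) {
  s <- work_split(ws)
  abort_if(length(s$wf) == 0L || length(s$wr) == 0L,
           "both directions must be non-empty")
  wrn <- -s$wr
  abort_if(max(s$wf) < min(wrn) || max(wrn) < min(s$wf),
           "insufficient overlap between work densities; use bar_estimate()")
  dg <- crooks_root(s$wf, wrn, bw_scale)
  se <- NA_real_
  if (n_boot > 0L) {
    boots <- with_seed_(seed, {
      vapply(seq_len(n_boot), function(b) {
        crooks_root(sample(s$wf, replace = TRUE),
                    sample(wrn, replace = TRUE), bw_scale)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  sens <- tibble::tibble(
    bw_scale = bw_scale * c(0.5, 1, 2),
    dG_kJ = vapply(bw_scale * c(0.5, 1, 2),
                   function(sc) crooks_root(s$wf, wrn, sc), numeric(1))
  )
  new_fep_estimate(dg, se, "crooks_kde", length(s$wf), length(s$wr),
                   s$temperature, sensitivity = sens,
                   label = attr(ws, "label"))
}

new_fep_estimate <- function(dG_kJ, stderr_kJ, method, n_F, n_R, temperature,
                             sensitivity = NULL, label = NULL,
                             flags = character()) {
  structure(
    list(dG_kJ = dG_kJ, dG_kT = dG_kJ / kBT_kJ(temperature),
         stderr_kJ = stderr_kJ, method = method, n_F = n_F, n_R = n_R,
         temperature = temperature, sensitivity = sensitivity,
         label = label, flags = flags),
    class = "fep_estimate"
  )
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf("<fep_estimate> %s: dG = %.4f kJ/mol (%.4f kT), se = %s, nF/nR = %d/%d\n",
              x$method, x$dG_kJ, x$dG_kT,
              ifelse(is.na(x$stderr_kJ), "NA", sprintf("%.4f", x$stderr_kJ)),
              x$n_F, x$n_R))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Bennett acceptance-ratio estimate
#'
#' Self-consistent solution of the BAR implicit equation by fixed-point
#' iteration (tolerance 1e-8 kJ/mol), used as an internal cross-check of the
#' Crooks intersection.  The standard error is the first-order Bennett
#' variance estimate; single-sample directions converge but are flagged
#' with an infinite standard error.
#'
#' @param ws A `work_set`.
#' @param tol Convergence tolerance, kJ/mol.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `fep_estimate` with `method = "bar"`.
#' @export
bar_estimate <- function(ws, tol = 1e-8, max_iter = 1e4) {
  s <- work_split(ws)
  abort_if(length(s$wf) == 0L || length(s$wr) == 0L,
           "both directions must be non-empty")
  kbt <- kBT_kJ(s$temperature)
  beta <- 1 / kbt
  wf <- s$wf
  wrn <- -s$wr                    # forward-convention equivalents
  nf <- length(wf); nr <- length(wrn)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))

  dg <- (mean(wf) + mean(wrn)) / 2
  for (it in seq_len(max_iter)) {
    num <- sum(fermi(-M - beta * (wrn - dg)))
    den <- sum(fermi(M + beta * (wf - dg)))
    step <- kbt * log(num / den)
    dg_new <- dg + step
    if (abs(dg_new - dg) < tol) { dg <- dg_new; break }
    dg <- dg_new
    if (it == max_iter) stop("BAR iteration did not converge", call. = FALSE)
  }

  flags <- character()
  if (nf < 2L || nr < 2L) {
    se <- Inf
    flags <- "single_sample_direction"
  } else {
    ff <- fermi(M + beta * (wf - dg))
    fr <- fermi(-M - beta * (wrn - dg))
    se2 <- (mean(ff^2) / mean(ff)^2 - 1) / nf +
      (mean(fr^2) / mean(fr)^2 - 1) / nr
    se <- sqrt(max(se2, 0)) * kbt
  }
  new_fep_estimate(dg, se, "bar", nf, length(s$wr), s$temperature,
                   label = attr(ws, "label"), flags = flags)
}

#' Combine single-strand and duplex estimates through thermodynamic cycles
#'
#' For each organic salt, the salt effect on a mutation is the difference of
#' its alchemical free energy in that salt and in the reference salt, for
#' the single-strand (ss) and duplex (ds) legs separately; the overall
#' effect on folding per mutated base pair is `(ddG_ds - ddG_ss) / n_subs`.
#' A one-sample t-test across mutation contexts tests whether the mean
#' overall effect differs from zero.
#'
#' @param ss,ds Tibbles with columns `salt`, `context`, `dG_kJ` for the
#'   single-strand and duplex legs (e.g. from [crooks_intersection()]
#'   results; one row per mutation context and salt).
#' @param n_subs Number of base pairs mutated in the duplex leg.
#' @param reference Reference salt label.
#' @param ss_per_substitution Also divide the ss leg by `n_subs`?  Off by
#'   default (only the duplex leg mutates both strands).
#' @return A `cycle_result`: tibble `salt, context, ddG_ss, ddG_ds,
#'   ddG_overall` with attribute `tests` (tibble `salt, mean_overall,
#'   t_stat, p_value, df`).
#' @export
combine_cycle <- function(ss, ds, n_subs = 2L, reference = "NaCl",
                          ss_per_substitution = FALSE) {
  check_leg <- function(x, who) {
    abort_if(!all(c("salt", "context", "dG_kJ") %in% names(x)),
             paste0("`", who, "` needs columns salt, context, dG_kJ"))
    tibble::as_tibble(x)
  }
  ss <- check_leg(ss, "ss"); ds <- check_leg(ds, "ds")
  abort_if(!reference %in% ss$salt || !reference %in% ds$salt,
           paste0("missing reference salt '", reference, "' in ss or ds"))

  diff_leg <- function(x) {
    ref <- x[x$salt == reference, c("context", "dG_kJ")]
    names(ref)[2L] <- "dG_ref"
    out <- dplyr::inner_join(x[x$salt != reference, ], ref, by = "context")
    dplyr::mutate(out, ddG = .data$dG_kJ - .data$dG_ref)[, c("salt", "context", "ddG")]
  }
  dss <- diff_leg(ss); names(dss)[3L] <- "ddG_ss"
  dds <- diff_leg(ds); names(dds)[3L] <- "ddG_ds"
  out <- dplyr::inner_join(dss, dds, by = c("salt", "context"))
  abort_if(nrow(out) == 0L, "no matching salt/context pairs between legs")
  if (ss_per_substitution) out$ddG_ss <- out$ddG_ss / n_subs
  out$ddG_overall <- (out$ddG_ds - out$ddG_ss) / n_subs

  tests <- out |>
    dplyr::group_by(.data$salt) |>
    dplyr::summarise(
      mean_overall = mean(.data$ddG_overall),
      t_stat = significance(.data$ddG_overall)["t_stat"],
      p_value = significance(.data$ddG_overall)["p_value"],
      df = dplyr::n() - 1L,
      .groups = "drop"
    )
  class(out) <- c("cycle_result", class(tibble::tibble()))
  attr(out, "tests") <- tests
  attr(out, "n_subs") <- n_subs
  attr(out, "reference") <- reference
  out
}

#' One-sample t-test of a mean against zero
#'
#' Two-sided test used for the per-salt overall free-energy effects.  A
#' zero-variance sample with nonzero mean is degenerate: `t = Inf`,
#' `p = 0`, flagged via attribute `degenerate`.
#'
#' @param values Numeric vector (length >= 2).
#' @return Named numeric `c(t_stat, p_value)` (attribute `degenerate` when
#'   the variance is zero).
#' @export
significance <- function(values) {
  abort_if(length(values) < 2L, "need at least 2 values")
  if (stats::sd(values) <= 1e-12 * max(abs(mean(values)), 1)) {
    m <- mean(values)
    out <- c(t_stat = if (m == 0) 0 else Inf * sign(m),
             p_value = if (m == 0) 1 else 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tt <- stats::t.test(values, mu = 0)
  c(t_stat = unname(tt$statistic), p_value = tt$p.value)
}
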