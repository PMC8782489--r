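#' Run analysis stages from a configuration
#'
#' Thin orchestration layer over the package's functions: reads a run
#' configuration (list or YAML file), executes the requested stages in
#' order and writes CSV/JSON results plus a manifest with input hashes and
#' parameters.  Available stages:
#' \describe{
#'   \item{melt}{Per-curve Tm by smoothed first derivative, then a van 't
#'     Hoff fit per condition with at least 3 strand concentrations.
#'     Config: `curves_dir` (directory of CSVs with `temperature`,
#'     `absorbance`), `ct_map` (CSV `file, ct_M, condition` plus optional
#'     `unit` column, "C" default), optional `window`, `order`, `t_ref`.}
#'   \item{fep}{Crooks intersection per work file, then thermodynamic
#'     cycles against a reference salt.  Config: `works_dir`, `works_map`
#'     (CSV `file, context, salt, leg` with leg ss/ds), optional
#'     `reference_salt` (default NaCl), `n_subs` (default 2).}
#' }
#'
#' @param config Named list or path to a YAML file with at least `stages`
#'   and `output_dir`.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "`config` must be a list or a YAML path")
  stages <- config$stages
  abort_if(is.null(stages) || length(stages) == 0L, "no stages requested")
  valid <- c("melt", "fep")
  bad <- setdiff(stages, valid)
  abort_if(length(bad) > 0L,
           paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                  "; valid stages are: ", paste(valid, collapse = ", ")))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  inputs <- character()

  if ("melt" %in% stages) {
    mc <- config$melt
    abort_if(is.null(mc$curves_dir) || is.null(mc$ct_map),
             "melt stage needs `curves_dir` and `ct_map`")
    map <- readr::read_csv(mc$ct_map, show_col_types = FALSE)
    abort_if(!all(c("file", "ct_M", "condition") %in% names(map)),
             "`ct_map` needs columns file, ct_M, condition")
    if (!"unit" %in% names(map)) map$unit <- "C"
    window <- mc$window %||% 11L
    order <- mc$order %||% 3L
    files <- file.path(mc$curves_dir, map$file)
    abort_if(!all(file.exists(files)),
             paste0("missing curve file(s): ",
                    paste(map$file[!file.exists(files)], collapse = ", ")))
    inputs <- c(inputs, files, mc$ct_map)
    tm_tbl <- purrr::pmap_dfr(
      list(files, map$ct_M, map$condition, map$unit),
      function(f, ct, cond, un) {
        crv <- read_melting_curve(f, unit = un, ct = ct, condition = cond)
        tibble::tibble(file = basename(f), condition = cond, ct_M = ct,
                       tm_K = find_tm(crv, window, order))
      }
    )
    readr::write_csv(tm_tbl, file.path(out_dir, "tm_table.csv"))
    thermo <- tm_tbl |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(function(d, key) {
        if (length(unique(d$ct_M)) < 3L) return(tibble::tibble())
        vf <- fit_vant_hoff(d, t_ref = config$melt$t_ref %||% 300)
        glance(vf)
      }) |>
      dplyr::ungroup()
    readr::write_csv(thermo, file.path(out_dir, "thermo_table.csv"))
    results$melt <- list(tm = tm_tbl, thermo = thermo)
  }

  if ("fep" %in% stages) {
    fc <- config$fep
    abort_if(is.null(fc$works_dir) || is.null(fc$works_map),
             "fep stage needs `works_dir` and `works_map`")
    map <- readr::read_csv(fc$works_map, show_col_types = FALSE)
    abort_if(!all(c("file", "context", "salt", "leg") %in% names(map)),
             "`works_map` needs columns file, context, salt, leg")
    files <- file.path(fc$works_dir, map$file)
    abort_if(!all(file.exists(files)), "missing work file(s)")
    inputs <- c(inputs, files, fc$works_map)
    est <- purrr::pmap_dfr(
      list(files, map$context, map$salt, map$leg),
      function(f, ctx, salt, leg) {
        ws <- read_work_values(f, label = paste(ctx, leg, salt))
        fe <- crooks_intersection(ws, n_boot = fc$n_boot %||% 200L,
                                  seed = config$seed %||% 1L)
        tibble::tibble(context = ctx, salt = salt, leg = leg,
                       dG_kJ = fe$dG_kJ, stderr_kJ = fe$stderr_kJ,
                       n_F = fe$n_F, n_R = fe$n_R)
      }
    )
    readr::write_csv(est, file.path(out_dir, "fep_estimates.csv"))
    cyc <- combine_cycle(est[est$leg == "ss", ], est[est$leg == "ds", ],
                         n_subs = fc$n_subs %||% 2L,
                         reference = fc$reference_salt %||% "NaCl")
    jsonlite::write_json(
      list(cycles = as.data.frame(cyc), tests = as.data.frame(attr(cyc, "tests"))),
      file.path(out_dir, "cycles.json"), auto_unbox = TRUE, digits = NA
    )
    results$fep <- list(estimates = est, cycles = cyc)
  }

  manifest <- list(
    package = "groovetherm",
    version = as.character(utils::packageVersion("groovetherm")),
    config = config,
    seed = config$seed %||% NA,
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs))),
    outputs = setdiff(list.files(out_dir), "manifest.json"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
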