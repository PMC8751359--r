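# Pipeline runner and report generation: thin, manifest-writing glue around
# the analysis functions, so every figure/table can be regenerated from a
# seed and a scale factor.

PIPELINES <- c("kd-sweep", "stoich-check", "ttfl-vs-ptr", "phospho-sweep",
               "sensitivity", "stoich-ratio", "detailed-run", "ssa-run")

# published full-size n per sampling pipeline
PAPER_N <- list(`kd-sweep` = 1e5, `ttfl-vs-ptr` = 22500,
                `phospho-sweep` = 1e4, `stoich-ratio` = 100)

#' Run a named analysis pipeline and write its result bundle
#'
#' Executes one of the package's analysis pipelines at a fraction `scale`
#' of the published sample size and writes CSV results, a JSON summary and
#' a manifest (configuration, seed, package version) into
#' `out_dir/<pipeline>/`.  Deterministic pipelines reproduce their outputs
#' bitwise when re-run with the same manifest.
#'
#' @param pipeline one of `r paste(PIPELINES, collapse = ", ")`.
#' @param seed integer master seed.
#' @param scale fraction of the published sample size in (0, 1].
#' @param out_dir output directory (created if needed).
#' @param config named list of pipeline-specific overrides (passed to the
#'   underlying analysis function).
#' @return the result bundle (list), invisibly; side effect: files on disk.
#' @examples
#' \donttest{
#' out <- run_pipeline("kd-sweep", seed = 1, scale = 0.0005,
#'                     out_dir = tempdir())
#' out$summary
#' }
#' @export
run_pipeline <- function(pipeline, seed = 1, scale = 0.1,
                         out_dir = "circlock-results", config = list()) {
  if (!pipeline %in% PIPELINES)
    stop_domain("unknown pipeline '", pipeline, "'; available: ",
                paste(PIPELINES, collapse = ", "))
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop_domain("'scale' must be in (0, 1]")
  dir <- file.path(out_dir, pipeline)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_of <- function(default) max(10, round(default * scale))

  bundle <- switch(pipeline,
    "kd-sweep" = {
      args <- modifyList(list(n = n_of(PAPER_N$`kd-sweep`), seed = seed),
                         config)
      sw <- do.call(kd_sweep_core, args)
      write.csv(sw$summary, file.path(dir, "fractions.csv"), row.names = FALSE)
      write.csv(sw$rows, file.path(dir, "rows.csv"), row.names = FALSE)
      list(pipeline = pipeline, summary = sw$summary, trend = sw$trend,
           result = sw)
    },
    "stoich-check" = {
      args <- modifyList(list(n = n_of(1e3), seed = seed,
                              kd_grid = logspace(1e-4, 1e-1, 14)), config)
      sw <- do.call(kd_sweep_core, args)
      chk <- stoich_condition_check(sw)
      write.csv(sw$rows, file.path(dir, "rows.csv"), row.names = FALSE)
      list(pipeline = pipeline,
           summary = data.frame(n_oscillating = chk$n_oscillating,
                                fraction_compliant = chk$fraction_compliant,
                                n_quiet_compliant = chk$n_quiet_compliant),
           result = chk)
    },
    "ttfl-vs-ptr" = {
      args <- modifyList(list(n = n_of(PAPER_N$`ttfl-vs-ptr`), seed = seed),
                         config)
      cmp <- do.call(ttfl_vs_ptr, args)
      write.csv(cmp$rows, file.path(dir, "paired_rows.csv"), row.names = FALSE)
      list(pipeline = pipeline,
           summary = data.frame(
             n = cmp$n,
             pct_ttfl = 100 * cmp$fraction_ttfl,
             pct_ptr = 100 * cmp$fraction_ptr,
             se_ttfl = 100 * cmp$se_ttfl, se_ptr = 100 * cmp$se_ptr),
           result = cmp)
    },
    "phospho-sweep" = {
      args <- modifyList(list(n = n_of(PAPER_N$`phospho-sweep`), seed = seed),
                         config)
      sw <- do.call(phospho_strength_sweep, args)
      write.csv(data.frame(Kd = sw$kd_grid, sw$percent, check.names = FALSE),
                file.path(dir, "percent.csv"), row.names = FALSE)
      list(pipeline = pipeline, summary = sw$percent, result = sw)
    },
    "sensitivity" = {
      kds <- config$kd_grid %||% c(1e-2, 1e-3, 1e-4)
      A_T <- config$A_T %||% 8
      grid <- seq(0.5 * A_T, 1.5 * A_T, length.out = 401)
      curves <- lapply(kds, function(kd)
        sensitivity_curve(function(S) free_kaia(S, A_T, kd), grid))
      peaks <- data.frame(Kd = kds,
                          peak = vapply(curves, attr, 0, "peak"),
                          peak_x = vapply(curves, attr, 0, "peak_x"))
      k2s <- config$k2_grid %||% c(1, 10, 100, 1e3, 1e4)
      pgrid <- seq(75, 150, length.out = 301)
      pcurves <- lapply(k2s, function(k2)
        sensitivity_curve(function(R)
          phospholock_repression(R, phospholock_params_table1(k2 = k2)),
          pgrid))
      ppeaks <- data.frame(k2 = k2s,
                           peak = vapply(pcurves, attr, 0, "peak"),
                           peak_x = vapply(pcurves, attr, 0, "peak_x"))
      write.csv(peaks, file.path(dir, "core_sensitivity_peaks.csv"),
                row.names = FALSE)
      write.csv(ppeaks, file.path(dir, "phospholock_sensitivity_peaks.csv"),
                row.names = FALSE)
      list(pipeline = pipeline,
           summary = list(core_peaks = peaks, phospholock_peaks = ppeaks),
           result = list(core = curves, phospholock = pcurves))
    },
    "stoich-ratio" = {
      args <- modifyList(list(target = n_of(PAPER_N$`stoich-ratio`),
                              seed = seed), config)
      sc <- do.call(stoich_ratio_distribution, args)
      write.csv(sc$summary, file.path(dir, "summary.csv"), row.names = FALSE)
      for (key in names(sc$tables))
        write.csv(sc$tables[[key]],
                  file.path(dir, paste0("sets_k3_", key, ".csv")),
                  row.names = FALSE)
      list(pipeline = pipeline, summary = sc$summary, result = sc)
    },
    "detailed-run" = {
      p <- do.call(detailed_params,
                   config[intersect(names(config),
                                    names(formals(detailed_params)))])
      tr <- simulate_detailed(p, t_end = config$t_end %||% 720)
      pf <- phospho_fraction(tr)
      v <- detect_oscillation_fft(pf, dt = tr$times[2] - tr$times[1])
      tau <- phase_durations(pf, times = tr$times)
      write_trajectory_csv(tr, file.path(dir, "trajectory.csv"))
      list(pipeline = pipeline,
           summary = data.frame(oscillating = v$oscillating,
                                period = v$period,
                                tau1 = tau[["tau1"]], tau2 = tau[["tau2"]]),
           result = list(verdict = v, tau = tau))
    },
    "ssa-run" = {
      p <- detailed_params()
      omega <- config$omega %||% 5
      net <- build_network(p)
      tr <- gillespie(net, t_end = config$t_end %||% 240, seed = seed,
                      omega = omega, dt_record = 0.1)
      write_trajectory_csv(tr, file.path(dir, "ssa_counts.csv"))
      list(pipeline = pipeline,
           summary = data.frame(omega = omega,
                                n_events = attr(tr, "n_events")),
           result = tr)
    })

  manifest <- list(pipeline = pipeline, seed = seed, scale = scale,
                   config = config,
                   package = as.character(packageVersion("circlock")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  summary_json <- bundle$summary
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       na = "null")
  bundle$dir <- dir
  bundle$manifest <- manifest
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# published reference values the report compares against
REPORT_TARGETS <- list(
  pct_ttfl = list(value = 98.84, tol = 3, unit = "%"),
  pct_ptr = list(value = 60.33, tol = 5, unit = "%"),
  tau1 = list(value = 9.5, tol = 1, unit = "h"),
  tau2 = list(value = 18.5, tol = 1, unit = "h"),
  period = list(value = 24, tol = 1.5, unit = "h"),
  fraction_compliant = list(value = 1.0, tol = 0.01, unit = "")
)

#' Summarise pipeline bundles against the published reference values
#'
#' Collates one or more [run_pipeline()] bundles into a single markdown +
#' JSON report that juxtaposes each computed quantity with its published
#' reference value and tolerance, marking each as pass/fail.  Regenerating
#' the report from the same bundles is byte-identical.
#'
#' @param bundles list of bundles returned by [run_pipeline()].
#' @param file optional markdown output path (a `.json` sibling is written
#'   alongside).
#' @return data frame of comparisons, invisibly when writing to file.
#' @export
make_report <- function(bundles, file = NULL) {
  if (length(bundles) == 0) stop_domain("no bundles given")
  if (!is.null(bundles$pipeline)) bundles <- list(bundles)
  rows <- list()
  for (b in bundles) {
    s <- b$summary
    if (is.data.frame(s)) {
      for (nm in intersect(names(s), names(REPORT_TARGETS))) {
        tg <- REPORT_TARGETS[[nm]]
        val <- s[[nm]][1]
        rows[[length(rows) + 1L]] <- data.frame(
          pipeline = b$pipeline, quantity = nm, computed = val,
          reference = tg$value, tolerance = tg$tol,
          pass = is.finite(val) && abs(val - tg$value) <= tg$tol)
      }
    }
  }
  if (!length(rows))
    stop_domain("bundles carry no reportable quantities")
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    lines <- c("# circlock pipeline report", "",
               "| pipeline | quantity | computed | reference | tol | verdict |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %s |",
                       out$pipeline, out$quantity, fmt_num(out$computed, 5),
                       fmt_num(out$reference, 5), fmt_num(out$tolerance),
                       ifelse(out$pass, "pass", "FAIL")))
    writeLines(lines, file)
    jsonlite::write_json(out, sub("\\.md$", ".json", file),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    return(invisible(out))
  }
  out
}
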