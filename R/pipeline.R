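# End-to-end orchestration: from a tree and a patient record to pre- and
# post-stent FFR and validation reports.

#' Configure a single simulation case
#'
#' @param tree A `coronary_tree`, or a path readable by [read_tree()].
#' @param patient A [patient_record()], or a named list/row with `sbp`,
#'   `dbp`, `lv_mass`.
#' @param sites List of [measurement_site()]s at which FFR is reported.
#' @param stents Optional list of [stent_spec()]s (deployed
#'   proximal-to-distal per branch); `NULL` skips the stenting stage.
#' @param hemo Named list of [hemo_params()] overrides.
#' @param solver Named list of [solver_settings()] overrides.
#' @param out_dir Optional output directory for the JSON/CSV report.
#' @param seed Seed recorded in (and controlling any randomness of) the run.
#' @param write_plots Also write agreement plots when `out_dir` is set.
#' @return An object of class `case_config`.
#' @export
case_config <- function(tree, patient, sites, stents = NULL,
                        hemo = list(), solver = list(), out_dir = NULL,
                        seed = 1L, write_plots = FALSE) {
  if (is.character(tree)) tree <- read_tree(tree)
  if (!inherits(patient, "patient_record"))
    patient <- patient_record(patient$sbp, patient$dbp, patient$lv_mass,
                              id = patient$id %||% NULL)
  if (inherits(sites, "measurement_site")) sites <- list(sites)
  if (inherits(stents, "stent_spec")) stents <- list(stents)
  structure(list(tree = tree, patient = patient, sites = sites,
                 stents = stents,
                 hemo = do.call(hemo_params, hemo),
                 solver = do.call(solver_settings, solver),
                 out_dir = out_dir, seed = as.integer(seed),
                 write_plots = isTRUE(write_plots)),
            class = "case_config")
}

#' Run one simulation case end-to-end
#'
#' Executes the full workflow: validate the tree, build patient-specific
#' boundary conditions, calibrate the outlet resistances to the hyperemic
#' inflow, solve, read FFR at each site; then, if stents are configured,
#' deploy them, rebuild and recalibrate the boundary conditions on the
#' stented anatomy (each simulation is self-contained), solve again and
#' read the post-stent FFR. The run is deterministic given the seed.
#'
#' @param config A [case_config()].
#' @return A case report list with `pre` and (when stented) `post` FFR
#'   tables, calibration diagnostics, and the configuration echo.
#' @export
run_case <- function(config) {
  if (!inherits(config, "case_config"))
    stop_coroflow("state_error", "run_case expects a case_config")
  with_seed(config$seed, {
    tree <- suppressWarnings(validate_tree(config$tree))
    stage <- function(tr, phase) {
      bc <- build_outlet_bcs(tr, config$patient, config$hemo)
      cal <- calibrate_total_flow(tr, bc$inlet_pressure, bc$bcs,
                                  bc$target_flow, config$solver, config$hemo)
      ffr <- lapply(config$sites, function(site)
        compute_ffrb(cal$solution, bc$inlet_pressure, site, phase = phase))
      list(
        ffr = data.frame(
          branch_id = vapply(ffr, function(f) f$site$branch_id, character(1)),
          s = vapply(ffr, function(f) f$site$s, numeric(1)),
          phase = phase,
          ffrb = vapply(ffr, function(f) f$ffrb, numeric(1)),
          ischemic = vapply(ffr, function(f) f$ischemic, logical(1))),
        calibration = list(beta = cal$beta,
                           outer_iterations = cal$outer_iterations,
                           inner_iterations = cal$solution$iterations,
                           residual = cal$solution$residual,
                           inlet_flow = cal$solution$inlet_flow,
                           target_flow = bc$target_flow,
                           inlet_pressure = bc$inlet_pressure))
    }
    pre <- stage(tree, "pre")
    post <- NULL
    if (!is.null(config$stents) && length(config$stents) > 0L) {
      stented <- tree
      ord <- order(vapply(config$stents, function(st) st$branch_id, character(1)),
                   vapply(config$stents, function(st) st$s_proximal, numeric(1)))
      for (st in config$stents[ord]) stented <- deploy_stent(stented, st)
      post <- stage(stented, "post")
      post$tree <- stented
    }
    report <- list(
      seed = config$seed,
      patient = unclass(config$patient),
      pre = pre["ffr"]$ffr, post = if (is.null(post)) NULL else post$ffr,
      calibration = list(pre = pre$calibration,
                         post = if (is.null(post)) NULL else post$calibration))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(report,
                           file.path(config$out_dir, "case_report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      ffr_all <- rbind(report$pre, report$post)
      utils::write.csv(ffr_all, file.path(config$out_dir, "ffr_results.csv"),
                       row.names = FALSE)
    }
    report
  })
}

#' Run a synthetic validation cohort end-to-end
#'
#' Generates the cohort, simulates every case pre- and post-stent, joins
#' the simulated FFR with the simulated invasive readings, and computes
#' the full agreement statistics (correlation, Bland-Altman, diagnostic
#' accuracy at the ischemia threshold) per phase.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory for the cohort CSVs, JSON report and
#'   plots.
#' @param threshold Ischemia threshold.
#' @param params A [hemo_params()] object.
#' @param settings A [solver_settings()] object.
#' @param write_plots Write scatter and Bland-Altman figures to `out_dir`.
#' @return A list with `paired`, `patients`, and per-phase `stats`.
#' @export
run_cohort <- function(spec, out_dir = NULL, threshold = 0.80,
                       params = hemo_params(), settings = solver_settings(),
                       write_plots = FALSE) {
  cohort <- generate_validation_cohort(spec, params, settings)
  stats_ <- agreement_report(cohort$paired, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort$paired, file.path(out_dir, "paired_ffr.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$patients, file.path(out_dir, "patients.csv"),
                     row.names = FALSE)
    report <- lapply(stats_, function(st) list(
      n = st$n, pearson = st$pearson,
      bland_altman = st$bland_altman[c("bias", "sd_diff", "loa_low",
                                       "loa_high", "n")],
      diagnostics = if (inherits(st$diagnostics, "diagnostic_metrics"))
        unclass(st$diagnostics) else st$diagnostics))
    jsonlite::write_json(report, file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(write_plots)) {
      ggplot2::ggsave(file.path(out_dir, "ffr_scatter.pdf"),
                      plot_ffr_agreement(cohort$paired, threshold),
                      width = 5, height = 5)
      for (ph in names(stats_)) {
        ggplot2::ggsave(
          file.path(out_dir, sprintf("bland_altman_%s.pdf", ph)),
          plot_bland_altman(stats_[[ph]]$bland_altman,
                            xlab = "Mean of simulated and invasive FFR",
                            ylab = "Simulated - invasive FFR"),
          width = 5, height = 4)
      }
    }
  }
  list(paired = cohort$paired, patients = cohort$patients, stats = stats_)
}
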