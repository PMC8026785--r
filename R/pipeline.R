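#' Read / write TAC tables
#'
#' Delimited text (comma or tab) with columns `frame_start_min`,
#' `frame_end_min`, then one column per region holding frame-mean activity in
#' kBq/cc. Header required.
#'
#' @param path File path.
#' @return `read_tac_table`: named list of [tac()] objects.
#' @export
read_tac_table <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("frame_start_min", "frame_end_min") %in% names(d)))
    stop("TAC table must have frame_start_min and frame_end_min columns")
  frames <- frame_schedule(d$frame_start_min, d$frame_end_min)
  regions <- setdiff(names(d), c("frame_start_min", "frame_end_min"))
  if (length(regions) == 0) stop("TAC table has no region columns")
  out <- lapply(regions, function(rg) tac(rg, frames, d[[rg]]))
  names(out) <- regions
  out
}

#' @rdname read_tac_table
#' @param tacs Named list of [tac()] objects sharing one frame schedule.
#' @export
write_tac_table <- function(tacs, path) {
  frames <- tacs[[1]]$frames
  d <- data.frame(frame_start_min = frames$start,
                  frame_end_min = frames$end)
  for (tc in tacs) d[[tc$region]] <- tc$values
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

fit_row <- function(f, subject, session) {
  p <- f$params
  data.frame(subject = subject, session = session, region = f$region,
             method = f$model,
             K1 = if (is.null(p)) NA_real_ else p$K1,
             k2 = if (is.null(p)) NA_real_ else p$k2,
             k3 = if (is.null(p)) NA_real_ else p$k3,
             k4 = if (is.null(p)) NA_real_ else p$k4,
             VT = f$VT, VND = f$VND, BPND = f$BPND,
             vt_percent_se = if (is.null(f$vt_percent_se)) NA_real_
                             else f$vt_percent_se,
             aic = f$aic, converged = f$converged, reliable = f$reliable,
             irreversible_limit = f$irreversible_limit,
             stringsAsFactors = FALSE)
}

graphical_row <- function(g, subject, session) {
  data.frame(subject = subject, session = session, region = g$region,
             method = g$method, K1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
             k4 = NA_real_, VT = g$VT, VND = NA_real_, BPND = NA_real_,
             vt_percent_se = NA_real_, aic = NA_real_, converged = TRUE,
             reliable = TRUE, irreversible_limit = FALSE,
             stringsAsFactors = FALSE)
}

#' Run the full quantification pipeline on a study
#'
#' For every subject and session: fits the parent-fraction model, builds the
#' metabolite-corrected input function, fits 1TCM and 2TCM per region, the
#' coupled 2TCM (shared V_ND across all non-composite regions), and Logan
#' (and optionally MA1) graphical analysis; then summarises test-retest
#' reliability per region and method, applying the %SE < 25% reliability
#' filter before all summaries.
#'
#' @param study A `synthetic_study` from [make_study()], or any list with the
#'   same shape (`subjects`, each holding `blood`, `pf_samples`, and `tacs` =
#'   named sessions of [tac()] lists).
#' @param methods Methods to run, subset of
#'   `c("1tcm", "2tcm", "2tcmc", "logan", "ma1")`.
#' @param tstar Graphical-analysis start time, minutes.
#' @param icc_type ICC variant for the reliability summary.
#' @return List with `estimates` (long data frame: subject, session, region,
#'   method, micro/macroparameters, %SE, flags), `reliability` (named list of
#'   per-region aTRV/ICC tables per method), and `manifest` (inputs, options,
#'   per-stage status).
#' @export
run_quantification <- function(study,
                               methods = c("1tcm", "2tcm", "2tcmc", "logan"),
                               tstar = 60,
                               icc_type = c("agreement", "consistency")) {
  icc_type <- match.arg(icc_type)
  methods <- match.arg(methods, c("1tcm", "2tcm", "2tcmc", "logan", "ma1"),
                       several.ok = TRUE)
  if (length(study$subjects) == 0) stop("study has no subjects")
  rows <- list()
  status <- list()
  for (sname in names(study$subjects)) {
    sub <- study$subjects[[sname]]
    res <- tryCatch({
      pf <- fit_parent_fraction(sub$pf_samples$time_min,
                                sub$pf_samples$parent_fraction)
      input <- build_mcaif(sub$blood, pf)
      for (sess in names(sub$tacs)) {
        tacs <- sub$tacs[[sess]]
        fit_regions <- tacs[setdiff(names(tacs), "whole_brain")]
        fits2t <- NULL
        if ("2tcm" %in% methods || "2tcmc" %in% methods)
          fits2t <- lapply(fit_regions, function(tc)
            fit_region("2tcm", tc, input))
        if ("1tcm" %in% methods)
          for (tc in fit_regions)
            rows[[length(rows) + 1L]] <-
              fit_row(fit_region("1tcm", tc, input), sname, sess)
        if ("2tcm" %in% methods)
          for (f in fits2t)
            rows[[length(rows) + 1L]] <- fit_row(f, sname, sess)
        if ("2tcmc" %in% methods) {
          cf <- fit_coupled(fit_regions, input, region_fits = fits2t)
          for (f in cf$per_region)
            rows[[length(rows) + 1L]] <- fit_row(f, sname, sess)
        }
        if ("logan" %in% methods)
          for (tc in fit_regions)
            rows[[length(rows) + 1L]] <-
              graphical_row(logan_fit(tc, input, tstar), sname, sess)
        if ("ma1" %in% methods)
          for (tc in fit_regions)
            rows[[length(rows) + 1L]] <-
              graphical_row(ma1_fit(tc, input, tstar), sname, sess)
      }
      "ok"
    }, error = function(e) paste("skipped:", conditionMessage(e)))
    status[[sname]] <- res
    if (res != "ok")
      message(sprintf("subject %s skipped: %s", sname, res))
  }
  if (length(rows) == 0) stop("no subject could be quantified")
  estimates <- do.call(rbind, rows)
  rel_methods <- intersect(methods, c("2tcmc", "logan", "2tcm", "1tcm", "ma1"))
  reliability <- lapply(rel_methods, function(m)
    reliability_table(estimates, m, icc_type))
  names(reliability) <- rel_methods
  list(estimates = estimates, reliability = reliability,
       manifest = list(package_version =
                         as.character(utils::packageVersion("petkin")),
                       methods = methods, tstar = tstar,
                       icc_type = icc_type, subject_status = status,
                       timestamp = format(Sys.time(), tz = "UTC")))
}

#' Run a displacement analysis
#'
#' Converts each arm's whole-brain TAC to SUV, normalises every curve to the
#' frame immediately preceding drug administration, averages the baseline
#' arms pointwise, and reports the percent displacement series and its value
#' at the configured evaluation time.
#'
#' @param baselines List of baseline [tac()] curves (>= 1).
#' @param displaced Displacement-arm [tac()].
#' @param metadata List with `injected_dose_MBq`, `body_weight_kg`, and
#'   `drug_time_min` (required), optionally `drug` and `dose` labels. Either
#'   one list shared by all arms or per-arm values of equal length.
#' @param eval_after Evaluation time, minutes post-drug (35 for a
#'   fast-penetrating competitor; 150 for a slow one).
#' @return List with `percent`, `series`, `normalized` (all arms), and
#'   `report` (one-row data frame).
#' @export
run_displacement <- function(baselines, displaced, metadata, eval_after = 35) {
  if (is.null(metadata$drug_time_min))
    stop("metadata must include drug_time_min")
  if (inherits(baselines, "tac")) baselines <- list(baselines)
  if (length(baselines) < 1) stop("at least one baseline arm is required")
  norm_arm <- function(tc)
    normalize_at(to_suv(tc, metadata$injected_dose_MBq,
                        metadata$body_weight_kg),
                 metadata$drug_time_min)
  nb <- lapply(baselines, norm_arm)
  nd <- norm_arm(displaced)
  pd <- percent_displacement(nb, nd, eval_after, metadata$drug_time_min)
  list(percent = pd$percent, series = pd$series,
       normalized = list(baselines = nb, displaced = nd),
       report = data.frame(region = displaced$region,
                           drug = metadata$drug %||% NA_character_,
                           dose = metadata$dose %||% NA_real_,
                           drug_time_min = metadata$drug_time_min,
                           eval_time_post_drug = eval_after,
                           pct_displacement = pd$percent,
                           stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a quantification report
#'
#' Flat CSV (one row per subject x session x region x method) and a JSON
#' mirror including the reliability tables and the run manifest.
#'
#' @param result Output of [run_quantification()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(result$estimates, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(estimates = result$estimates,
                              reliability = result$reliability,
                              manifest = result$manifest),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
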