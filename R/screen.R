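# End-to-end drug screen: single-cell panel -> tissue + forward ECG ->
# biomarker report, with a reproducibility manifest.

#' Screening configuration
#'
#' @param drugs Character vector of drug names from the drug table (default:
#'   all bundled drugs); empty vector runs the control only.
#' @param multipliers Cmax multipliers, default \code{c(1, 5, 10)}.
#' @param drug_table Named list of \code{drugRecord}s (default: bundled).
#' @param geometry \code{"cable"} (default) or any \code{tissueModel}.
#' @param cl Cycle length (ms), default 1000.
#' @param prepace_beats Single-cell pre-pacing beats, default 50.
#' @param n_beats Tissue beats per condition, default 2.
#' @param run_tissue Compute tissue ECG biomarkers (default TRUE); FALSE
#'   restricts the screen to the single-cell panel.
#' @param forward Forward model, \code{"homogeneous"} or \code{"bem"}.
#' @param correction Rate-correction method for QTc/JTpeak_c.
#' @param out_dir Output directory for report/manifest files (NULL: no files).
#' @return Object of class \code{screenConfig}.
#' @export
screenConfig <- function(drugs = NULL, multipliers = c(1, 5, 10),
                         drug_table = loadDrugTable(),
                         geometry = "cable", cl = 1000,
                         prepace_beats = 50, n_beats = 2,
                         run_tissue = TRUE,
                         forward = "homogeneous",
                         correction = "fridericia", out_dir = NULL) {
  if (is.null(drugs)) drugs <- names(drug_table)
  missing_drugs <- setdiff(drugs, names(drug_table))
  if (length(missing_drugs))
    stop("drug(s) not in table: ", paste(missing_drugs, collapse = ", "))
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  structure(list(drugs = drugs, multipliers = multipliers,
                 drug_table = drug_table, geometry = geometry, cl = cl,
                 prepace_beats = prepace_beats, n_beats = n_beats,
                 run_tissue = run_tissue, forward = forward,
                 correction = correction, out_dir = out_dir),
            class = "screenConfig")
}

.config_hash <- function(config) {
  # deterministic config fingerprint without external digest packages
  txt <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "drug_table")])), collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Run a drug screen
#'
#' Stages per drug and concentration multiplier: channel scalings via the
#' Hill equation; single-cell panel (delta-APD90 per cell type, TDR, EAD /
#' repolarization-failure flags); optionally cable tissue simulation with
#' forward ECG and interval extraction (delta-QTc, delta-JTpeak_c, VT flag).
#' Partial failures (non-repolarizing cells, unmeasurable T waves) are
#' recorded as NA markers and the run continues.
#'
#' @param config A \code{\link{screenConfig}}.
#' @param quiet Suppress progress messages.
#' @return Object of class \code{biomarkerReport}: data.frame \code{table}
#'   (one row per drug x multiplier plus a control row), \code{manifest}
#'   metadata, and the per-condition details.
#' @export
runScreen <- function(config = screenConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "screenConfig"))
  t_start <- Sys.time()
  model <- if (inherits(config$geometry, "tissueModel")) config$geometry
    else buildCable()
  cache <- new.env(parent = emptyenv())
  prot <- pacingProtocol(cl = config$cl, n_beats = config$prepace_beats,
                         steady_tolerance = 0)
  stage_log <- list()
  log_stage <- function(stage, t0, outcome = "ok") {
    stage_log[[length(stage_log) + 1]] <<- list(
      stage = stage, seconds = round(as.numeric(Sys.time() - t0, "secs"), 2),
      outcome = outcome)
    if (!quiet) message(sprintf("[%s] %s (%.1fs)", outcome, stage,
                                as.numeric(Sys.time() - t0, "secs")))
  }

  single_cell <- function(scalings) {
    lapply(c(endo = "endo", M = "M", epi = "epi"), function(ty)
      paceToSteadyState(ty, scalings, prot))
  }
  t0 <- Sys.time()
  ctrl <- single_cell(drugScalings(NULL))
  log_stage("control single-cell panel", t0)
  ctrl_apd <- vapply(ctrl, function(x) tail(x$apd90, 1), numeric(1))
  ctrl_tdr <- tdr(ctrl_apd[["endo"]], ctrl_apd[["M"]], ctrl_apd[["epi"]])

  ctrl_ecg <- NULL
  if (config$run_tissue) {
    t0 <- Sys.time()
    ctrl_ecg <- cableEcgRun(model, drugScalings(NULL), cl = config$cl,
                            n_beats = config$n_beats,
                            prepace_beats = config$prepace_beats,
                            prepace_cache = cache)
    log_stage("control tissue + forward ECG", t0)
  }
  rr <- config$cl
  ctrl_qtc <- if (!is.null(ctrl_ecg) && !is.na(ctrl_ecg$intervals$qt))
    rateCorrect(ctrl_ecg$intervals$qt, rr, config$correction) else NA_real_
  ctrl_jtp_c <- if (!is.null(ctrl_ecg) && !is.na(ctrl_ecg$intervals$jtpeak))
    rateCorrect(ctrl_ecg$intervals$jtpeak, rr, config$correction) else NA_real_

  rows <- list()
  rows[[1]] <- data.frame(
    drug = "control", multiplier = 0,
    dAPD90_endo = 0, dAPD90_M = 0, dAPD90_epi = 0, dTDR = 0,
    dQTc = if (config$run_tissue) 0 else NA_real_,
    dJTpeak_c = if (config$run_tissue) 0 else NA_real_,
    ead_or_failure = "none", vt = FALSE)
  details <- list()

  for (dg in config$drugs) {
    for (mult in config$multipliers) {
      cond <- sprintf("%s %gx", dg, mult)
      t0 <- Sys.time()
      res <- tryCatch({
        sc <- drugScalings(config$drug_table[[dg]], mult)
        panel <- single_cell(sc)
        apd_d <- vapply(panel, function(x) tail(x$apd90, 1), numeric(1))
        flags <- vapply(panel, detectEadOrFailure, character(1))
        worst <- if (any(flags == "repolarization_failure"))
          "repolarization_failure" else if (any(flags == "EAD")) "EAD"
          else "none"
        d_tdr <- tdr(apd_d[["endo"]], apd_d[["M"]], apd_d[["epi"]]) - ctrl_tdr
        d_qtc <- d_jtp <- NA_real_
        vt <- FALSE
        ecg_run <- NULL
        if (config$run_tissue) {
          ecg_run <- cableEcgRun(model, sc, cl = config$cl,
                                 n_beats = config$n_beats,
                                 prepace_beats = config$prepace_beats,
                                 prepace_cache = cache)
          iv <- ecg_run$intervals
          if (!is.na(iv$qt))
            d_qtc <- rateCorrect(iv$qt, rr, config$correction) - ctrl_qtc
          if (!is.na(iv$jtpeak))
            d_jtp <- rateCorrect(iv$jtpeak, rr, config$correction) - ctrl_jtp_c
          if (!is.null(ctrl_ecg) && !is.na(ctrl_ecg$intervals$qt))
            vt <- detectVt(ecg_run$ecg, ctrl_ecg$intervals$qt,
                           recording = ecg_run$recording)
        }
        list(row = data.frame(
          drug = dg, multiplier = mult,
          dAPD90_endo = apd_d[["endo"]] - ctrl_apd[["endo"]],
          dAPD90_M = apd_d[["M"]] - ctrl_apd[["M"]],
          dAPD90_epi = apd_d[["epi"]] - ctrl_apd[["epi"]],
          dTDR = d_tdr, dQTc = d_qtc, dJTpeak_c = d_jtp,
          ead_or_failure = worst, vt = vt),
          panel = panel, ecg_run = ecg_run)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log_stage(cond, t0, outcome = paste("error:", conditionMessage(res)))
        rows[[length(rows) + 1]] <- data.frame(
          drug = dg, multiplier = mult, dAPD90_endo = NA_real_,
          dAPD90_M = NA_real_, dAPD90_epi = NA_real_, dTDR = NA_real_,
          dQTc = NA_real_, dJTpeak_c = NA_real_,
          ead_or_failure = "error", vt = NA)
      } else {
        log_stage(cond, t0)
        rows[[length(rows) + 1]] <- res$row
        details[[cond]] <- res[c("panel", "ecg_run")]
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  manifest <- list(config_hash = .config_hash(config),
                   version = as.character(utils::packageVersion("cardioscreen")),
                   correction = config$correction,
                   cl_ms = config$cl, prepace_beats = config$prepace_beats,
                   stages = stage_log,
                   wall_time_s = round(as.numeric(Sys.time() - t_start,
                                                  "secs"), 2))
  report <- structure(list(table = tab, manifest = manifest,
                           control = list(apd90 = ctrl_apd, tdr = ctrl_tdr,
                                          qtc = ctrl_qtc,
                                          jtpeak_c = ctrl_jtp_c),
                           details = details),
                      class = "biomarkerReport")
  if (!is.null(config$out_dir)) writeReport(report, config$out_dir)
  report
}

#' @export
print.biomarkerReport <- function(x, ...) {
  cat("<biomarkerReport> ", nrow(x$table), " condition row(s); control APD90 ",
      paste(round(x$control$apd90, 1), collapse = "/"),
      " ms (endo/M/epi)\n", sep = "")
  df <- x$table
  for (col in c("dAPD90_endo", "dAPD90_M", "dAPD90_epi", "dTDR", "dQTc",
                "dJTpeak_c"))
    df[[col]] <- ifelse(is.na(df[[col]]), "-", round(df[[col]], 0))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a biomarker report (CSV + JSON + manifest)
#'
#' The CSV mirrors the drug x concentration layout of the report table with
#' "-" marking measurement failures; the JSON carries the full report and the
#' manifest includes per-file checksums.
#'
#' @param report A \code{biomarkerReport}.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "biomarker_report.csv")
  tab <- report$table
  for (col in names(tab))
    if (is.numeric(tab[[col]])) tab[[col]] <- ifelse(is.na(tab[[col]]), "-",
                                                     format(tab[[col]]))
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  js <- file.path(dir, "biomarker_report.json")
  jsonlite::write_json(list(table = report$table,
                            control = report$control,
                            manifest = report$manifest),
                       js, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  manifest_path <- file.path(dir, "manifest.json")
  files <- c(csv, js)
  manifest <- c(report$manifest,
                list(files = data.frame(path = basename(files),
                                        md5 = unname(tools::md5sum(files)))))
  jsonlite::write_json(manifest, manifest_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(c(files, manifest_path))
}
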