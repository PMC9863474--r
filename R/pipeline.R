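# End-to-end orchestration: scoring runs, full study runs, reports and logs.
# Human-readable output rounds ratios to 2 decimals; machine-readable files
# keep full precision.

# polynomial rolling hash (hex) for config fingerprints in run logs
.config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_run_log <- function(dir, config, counts) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  writeLines(as.character(cfg_json), file.path(dir, "config.json"))
  lines <- c(
    paste0("papvrscore ", as.character(utils::packageVersion("papvrscore"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("config_hash ", .config_hash(as.character(cfg_json))),
    paste0("seed ", if (is.null(config$seed)) "NA" else config$seed),
    vapply(names(counts), function(nm) paste0("records_", nm, " ", counts[[nm]]),
           character(1))
  )
  writeLines(lines, file.path(dir, "run_log.txt"))
  invisible(NULL)
}

# resolve a run_score/run_study input into a scored-ready cohort data.frame
.resolve_cohort <- function(input, snap = FALSE, model = NULL,
                            lenient = FALSE) {
  if (is.data.frame(input)) return(input)
  if (is.character(input) && length(input) == 1L) {
    if (dir.exists(input)) {
      files <- sort(list.files(input, pattern = "\\.(lmk|txt)$",
                               full.names = TRUE))
      if (!length(files)) {
        stop("no landmark annotation files (*.lmk, *.txt) in ", input,
             call. = FALSE)
      }
      anatomies <- lapply(files, read_landmarks)
      if (snap) {
        if (is.null(model)) {
          stop("snapping requested but no surface model given", call. = FALSE)
        }
        mesh <- read_stl(model)
        anatomies <- lapply(anatomies, snap_to_surface, mesh = mesh)
      }
      return(measure_cohort(anatomies))
    }
    return(read_cohort(input, lenient = lenient))
  }
  stop("`input` must be a cohort data.frame, a cohort-table path, or a ",
       "directory of landmark files", call. = FALSE)
}

#' Score a cohort end to end
#'
#' Reads a cohort (distance table, landmark-annotation directory, or an
#' in-memory data.frame), computes per-patient PAPVR ratios and, when a
#' cutoff is supplied, predicted procedures. Deterministic for fixed input:
#' re-running with the same configuration reproduces all output files
#' exactly.
#'
#' @param input Cohort table path, directory of landmark files, or
#'   `data.frame` with the cohort-table columns.
#' @param cutoff Optional fixed decision threshold in (0, 1).
#' @param output_dir Optional directory; when given, writes `scores.tsv`
#'   (full precision), `config.json` and `run_log.txt`.
#' @param snap Snap landmarks to the surface model before measuring
#'   (landmark-directory input only).
#' @param model Path to an STL surface model, required when `snap = TRUE`.
#' @param lenient Skip malformed cohort rows with a warning instead of
#'   aborting.
#' @return The scored cohort `data.frame`, invisibly when writing.
#' @export
run_score <- function(input, cutoff = NULL, output_dir = NULL, snap = FALSE,
                      model = NULL, lenient = FALSE) {
  if (!is.null(cutoff) && (cutoff <= 0 || cutoff >= 1)) {
    stop("fixed `cutoff` must lie strictly in (0, 1)", call. = FALSE)
  }
  cohort <- .resolve_cohort(input, snap = snap, model = model,
                            lenient = lenient)
  scored <- score_cohort(cohort, cutoff)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scored, file.path(output_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_run_log(
      output_dir,
      list(command = "score", cutoff = cutoff, snap = snap, seed = NULL,
           input = if (is.character(input)) input else "<data.frame>"),
      list(scored = nrow(scored))
    )
    return(invisible(scored))
  }
  scored
}

#' Run the full decision-analysis study
#'
#' Executes the complete pipeline on a labelled cohort: measure/score, build
#' the Warden-vs-patch ROC curve, select the Youden-optimal cutoff (unless a
#' fixed one is given), summarize per-procedure score distributions, compare
#' groups, and tabulate the confusion matrix at the operating cutoff.
#'
#' @param input Cohort source as in [run_score()]; must carry
#'   `actual_procedure` labels with both Warden and patch patients present.
#'   Alternatively `NULL` with `spec` given.
#' @param spec Optional [cohort_spec()]: simulate a fresh synthetic cohort
#'   and analyze it (the `--simulate` path). Ignored when `input` is given.
#' @param cutoff Optional fixed cutoff; when `NULL` the Youden-optimal
#'   cutoff derived from the data is used.
#' @param output_dir Optional directory; when given, writes `report.json`
#'   (full-precision machine-readable report), `roc_table.tsv`,
#'   `summary.txt` (ratios rounded to 2 decimals), `scores.tsv`,
#'   `config.json` and `run_log.txt`.
#' @return Object of class `papvr_study`: list with `scored`, `roc`,
#'   `cutoff`, `cutoff_source`, `confusion`, `summary`, `warden_vs_patch`
#'   (binary group comparison).
#' @export
#' @examples
#' st <- run_study(spec = cohort_spec(seed = 42, group_sizes = c(7, 8, 15)))
#' st$cutoff
run_study <- function(input = NULL, spec = NULL, cutoff = NULL,
                      output_dir = NULL) {
  if (!is.null(cutoff) && (cutoff <= 0 || cutoff >= 1)) {
    stop("fixed `cutoff` must lie strictly in (0, 1)", call. = FALSE)
  }
  seed <- NULL
  if (is.null(input)) {
    if (is.null(spec)) stop("give `input` or `spec`", call. = FALSE)
    syn <- sample_cohort(spec)
    seed <- spec$seed
    cohort <- measure_cohort(syn$anatomies)
    cohort$actual_procedure <- syn$cohort$actual_procedure
  } else {
    cohort <- .resolve_cohort(input)
  }
  if (!"actual_procedure" %in% names(cohort)) {
    stop("study requires `actual_procedure` labels", call. = FALSE)
  }
  scored <- score_cohort(cohort)

  roc <- tryCatch(
    roc_curve(scored$ratio, scored$actual_procedure),
    error = function(e) {
      stop("cannot derive a cutoff from this cohort: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(cutoff)) {
    sel <- optimal_cutoff(roc)
    # sentinel thresholds can sit just outside (0, 1); clamp the operating
    # point into the classifiable range
    cutoff <- min(max(sel$cutoff, 1e-9), 1 - 1e-9)
    cutoff_source <- "youden"
  } else {
    cutoff_source <- "fixed"
  }
  scored$predicted_procedure <-
    as.character(classify_procedure(scored$ratio, cutoff))
  confusion <- confusion_at(scored$ratio, scored$actual_procedure, cutoff)
  summary <- summarize_cohort(scored$ratio, scored$actual_procedure)
  wvp <- compare_groups(scored$ratio,
                        collapse_procedure(scored$actual_procedure))

  study <- structure(
    list(scored = scored, roc = roc, cutoff = cutoff,
         cutoff_source = cutoff_source, confusion = confusion,
         summary = summary, warden_vs_patch = wvp, seed = seed),
    class = "papvr_study"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scored, file.path(output_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roc$table, file.path(output_dir, "roc_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(
      cutoff = cutoff,
      cutoff_source = cutoff_source,
      auc = roc$auc,
      optimal = roc$optimal,
      confusion = unclass(confusion),
      groups = summary$groups,
      warden_vs_patch = wvp
    )
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    txt <- c(
      "PAPVR decision-analysis study",
      sprintf("operating cutoff: %.2f (%s)", cutoff, cutoff_source),
      sprintf("AUC: %.2f", roc$auc),
      sprintf("confusion at cutoff: TP=%d FP=%d TN=%d FN=%d (sens %.2f, spec %.2f)",
              confusion$tp, confusion$fp, confusion$tn, confusion$fn,
              confusion$sensitivity, confusion$specificity),
      utils::capture.output(print(summary))
    )
    writeLines(txt, file.path(output_dir, "summary.txt"))
    .write_run_log(
      output_dir,
      list(command = "study", cutoff = cutoff, cutoff_source = cutoff_source,
           seed = seed,
           input = if (is.character(input)) input else
             if (is.null(input)) "<simulated>" else "<data.frame>"),
      list(scored = nrow(scored), thresholds = nrow(roc$table))
    )
    return(invisible(study))
  }
  study
}

#' @export
print.papvr_study <- function(x, ...) {
  cat("<papvr_study>\n")
  cat(sprintf("operating cutoff %.2f (%s), AUC %.2f\n",
              x$cutoff, x$cutoff_source, x$roc$auc))
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d (sens %.2f, spec %.2f)\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn,
              x$confusion$sensitivity, x$confusion$specificity))
  print(x$summary)
  cat(sprintf("Warden vs patch (%s): p = %.3g\n",
              x$warden_vs_patch$method, x$warden_vs_patch$p_value))
  invisible(x)
}
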