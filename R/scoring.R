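# PAPVR ratio computation, surgical classification, cohort-table I/O.

#' Surgical procedure labels
#'
#' Three procedures correct right PAPVR: baffling of the anomalous veins
#' through the sinus venosus defect with one patch (`SINGLE_PATCH`), baffling
#' plus caval enlargement with a second patch (`DOUBLE_PATCH`), and caval
#' transection with reimplantation into the atrial appendage (`WARDEN`).
#' The cutoff analysis is binary: Warden versus either patch repair.
#'
#' @return Character vector of the three procedure labels.
#' @export
surgical_labels <- function() c("SINGLE_PATCH", "DOUBLE_PATCH", "WARDEN")

#' Collapse procedure labels to the Warden-vs-patch dichotomy
#'
#' @param label Character vector of labels from [surgical_labels()], or
#'   already-collapsed `"PATCH"`/`"WARDEN"`.
#' @return Factor with levels `PATCH`, `WARDEN`.
#' @export
#' @examples
#' collapse_procedure(c("SINGLE_PATCH", "DOUBLE_PATCH", "WARDEN"))
collapse_procedure <- function(label) {
  label <- as.character(label)
  ok <- label %in% c(surgical_labels(), "PATCH")
  if (any(!ok)) {
    stop("unknown procedure label(s): ",
         paste(unique(label[!ok]), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(label == "WARDEN", "WARDEN", "PATCH")
  factor(out, levels = c("PATCH", "WARDEN"))
}

#' Compute the PAPVR ratio
#'
#' The score is the normalized position of the most cranial anomalous
#' pulmonary vein along the caval axis:
#' `d_pv_svd / (d_pv_svd + d_pv_azygos)`, with both distances in mm.
#' The ratio is dimensionless, confined to \[0, 1\] and invariant under
#' rescaling of the anatomy, which is what makes it applicable across
#' patient sizes.
#'
#' @param d_pv_svd Distance (mm) from the cranial anomalous pulmonary vein to
#'   the superior rim of the sinus venosus defect; or a `measurement_set`
#'   from [measure_anatomy()], in which case `d_pv_azygos` is ignored.
#' @param d_pv_azygos Distance (mm) from the same vein to the inferior rim of
#'   the azygos vein.
#' @return Numeric vector of ratios in \[0, 1\].
#' @export
#' @examples
#' papvr_ratio(10, 10)   # 0.5
#' papvr_ratio(30, 10)   # 0.75
#' papvr_ratio(0, 12)    # 0: vein at the defect
papvr_ratio <- function(d_pv_svd, d_pv_azygos) {
  if (inherits(d_pv_svd, "measurement_set")) {
    m <- d_pv_svd
    d_pv_svd <- m$d_pv_svd
    d_pv_azygos <- m$d_pv_azygos
  }
  d_pv_svd <- as.numeric(d_pv_svd)
  d_pv_azygos <- as.numeric(d_pv_azygos)
  if (length(d_pv_svd) != length(d_pv_azygos)) {
    stop("`d_pv_svd` and `d_pv_azygos` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(d_pv_svd)) || any(!is.finite(d_pv_azygos))) {
    stop("distances must be finite", call. = FALSE)
  }
  if (any(d_pv_svd < 0) || any(d_pv_azygos < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  total <- d_pv_svd + d_pv_azygos
  if (any(total <= 0)) {
    stop("undefined score: d_pv_svd + d_pv_azygos must be positive",
         call. = FALSE)
  }
  d_pv_svd / total
}

#' Classify the predicted surgical procedure from the PAPVR ratio
#'
#' A ratio strictly above the cutoff predicts a Warden procedure (the
#' anomalous vein sits far from the defect, close to the azygos vein);
#' otherwise a single/double patch repair. The tie at exactly the cutoff is
#' resolved to `PATCH` (the rule is strictly "above").
#'
#' @param ratio Numeric vector of PAPVR ratios in \[0, 1\].
#' @param cutoff Decision threshold, strictly in (0, 1). Default 0.68, the
#'   published operating point.
#' @return Factor with levels `PATCH`, `WARDEN`.
#' @export
#' @examples
#' classify_procedure(c(0.99, 0.82, 0.88))        # all WARDEN
#' classify_procedure(0.68)                       # PATCH: strict inequality
classify_procedure <- function(ratio, cutoff = 0.68) {
  ratio <- as.numeric(ratio)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff >= 1) {
    stop("`cutoff` must be a single number strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 1)) {
    stop("`ratio` must lie in [0, 1]", call. = FALSE)
  }
  factor(ifelse(ratio > cutoff, "WARDEN", "PATCH"),
         levels = c("PATCH", "WARDEN"))
}

# required cohort-table columns; actual_procedure is optional
.COHORT_COLS <- c("patient_id", "d_pv_svd_mm", "d_pv_azygos_mm")

#' Read a cohort table of per-patient distances
#'
#' Strict delimited-text reader (tab or comma, detected from the header
#' line). Required columns: `patient_id`, `d_pv_svd_mm`, `d_pv_azygos_mm`;
#' optional: `actual_procedure` (values from [surgical_labels()] or
#' `"PATCH"`). In strict mode (default) any malformed row aborts with its
#' line number; with `lenient = TRUE` malformed rows are dropped with a
#' warning.
#'
#' @param path Path to the delimited table.
#' @param lenient Drop malformed rows instead of failing.
#' @return `data.frame` with validated columns.
#' @export
read_cohort <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(.COHORT_COLS, names(df))
  if (length(missing)) {
    stop("cohort table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("cohort table has no data rows", call. = FALSE)

  d1 <- suppressWarnings(as.numeric(df$d_pv_svd_mm))
  d2 <- suppressWarnings(as.numeric(df$d_pv_azygos_mm))
  bad <- !is.finite(d1) | !is.finite(d2) | d1 < 0 | d2 < 0 | (d1 + d2) <= 0 |
    !nzchar(df$patient_id)
  has_actual <- "actual_procedure" %in% names(df)
  if (has_actual) {
    bad <- bad | !(df$actual_procedure %in% c(surgical_labels(), "PATCH"))
  }
  if (any(bad)) {
    rows <- which(bad) + 1L  # +1: header line
    if (!lenient) {
      stop("malformed cohort row(s) at line(s): ",
           paste(rows, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(rows, collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    d1 <- d1[!bad]
    d2 <- d2[!bad]
    if (nrow(df) == 0L) stop("no valid rows remain", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id) > 0L) {
    stop("duplicate patient_id in cohort table", call. = FALSE)
  }
  out <- data.frame(patient_id = df$patient_id, d_pv_svd_mm = d1,
                    d_pv_azygos_mm = d2, stringsAsFactors = FALSE)
  if (has_actual) out$actual_procedure <- df$actual_procedure
  out
}

#' Write a cohort table
#'
#' Tab-delimited, full precision; the same dialect [read_cohort()] accepts.
#'
#' @param cohort `data.frame` with the cohort-table columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(.COHORT_COLS, names(cohort))
  if (length(missing)) {
    stop("cohort lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score a cohort table
#'
#' Adds the PAPVR ratio and, when a cutoff is supplied, the predicted
#' procedure to a cohort table of distances.
#'
#' @param cohort `data.frame` as returned by [read_cohort()] or
#'   [measure_cohort()].
#' @param cutoff Optional decision threshold in (0, 1); when `NULL`, only
#'   ratios are computed.
#' @return The input with a `ratio` column (full precision) and, if `cutoff`
#'   given, `predicted_procedure`.
#' @export
score_cohort <- function(cohort, cutoff = NULL) {
  missing <- setdiff(.COHORT_COLS, names(cohort))
  if (length(missing)) {
    stop("cohort lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cohort$ratio <- papvr_ratio(cohort$d_pv_svd_mm, cohort$d_pv_azygos_mm)
  if (!is.null(cutoff)) {
    cohort$predicted_procedure <-
      as.character(classify_procedure(cohort$ratio, cutoff))
  }
  cohort
}
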