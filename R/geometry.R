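# Landmark geometry: anatomy containers, annotation I/O, distance measurement.

# minimum separation (mm) below which two landmarks count as coincident
.DISTINCT_TOL <- 1e-6

#' Names of the three anatomical landmarks of the PAPVR score
#'
#' The score is built from three reference points identified on a 3D
#' reconstructed model: the superior rim of the most cranial anomalous
#' pulmonary vein, the superior rim of the sinus venosus defect, and the
#' inferior rim of the azygos vein.
#'
#' @return Character vector of the three landmark identifiers, in canonical
#'   order: `"PV_CRANIAL_SUPERIOR_RIM"`, `"SVD_SUPERIOR_RIM"`,
#'   `"AZYGOS_INFERIOR_RIM"`.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  c("PV_CRANIAL_SUPERIOR_RIM", "SVD_SUPERIOR_RIM", "AZYGOS_INFERIOR_RIM")
}

#' Construct a patient anatomy from three named landmarks
#'
#' @param patient_id Single non-empty string.
#' @param landmarks Numeric 3x3 matrix of landmark coordinates in
#'   millimetres, one row per landmark, rownames exactly
#'   [landmark_names()] (any order), columns x/y/z.
#' @param model_path Optional path to an associated surface model (STL).
#'
#' @return An object of class `patient_anatomy`: a list with elements
#'   `patient_id`, `landmarks` (rows reordered to canonical order) and
#'   `model_path`.
#'
#' @details Validity requires finite coordinates, exactly one landmark per
#'   name, and pairwise separations strictly greater than 1e-6 mm.
#'   Coordinates are right-handed Cartesian millimetres; voxel/image-space
#'   coordinates are not accepted (conversion is upstream).
#' @export
#' @examples
#' lm <- rbind(
#'   PV_CRANIAL_SUPERIOR_RIM = c(0, 0, 0),
#'   SVD_SUPERIOR_RIM        = c(0, 0, 10),
#'   AZYGOS_INFERIOR_RIM     = c(0, 0, 25)
#' )
#' patient_anatomy("P001", lm)
patient_anatomy <- function(patient_id, landmarks, model_path = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id)) {
    stop("`patient_id` must be a single non-empty string", call. = FALSE)
  }
  landmarks <- as.matrix(landmarks)
  storage.mode(landmarks) <- "double"
  if (!identical(dim(landmarks), c(3L, 3L))) {
    stop("`landmarks` must be a 3x3 numeric matrix (one row per landmark)",
         call. = FALSE)
  }
  nm <- rownames(landmarks)
  canonical <- landmark_names()
  if (is.null(nm) || anyDuplicated(nm) > 0L || !setequal(nm, canonical)) {
    missing <- setdiff(canonical, nm)
    if (length(missing)) {
      stop("missing landmark(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    stop("landmark rownames must be exactly {",
         paste(canonical, collapse = ", "), "} with no duplicates",
         call. = FALSE)
  }
  if (!all(is.finite(landmarks))) {
    stop("landmark coordinates must all be finite", call. = FALSE)
  }
  landmarks <- landmarks[canonical, , drop = FALSE]
  colnames(landmarks) <- c("x", "y", "z")
  d <- as.matrix(stats::dist(landmarks))
  if (any(d[upper.tri(d)] <= .DISTINCT_TOL)) {
    stop("landmark positions must be pairwise distinct (separation > 1e-6 mm)",
         call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, landmarks = landmarks,
         model_path = model_path),
    class = "patient_anatomy"
  )
}

#' @export
print.patient_anatomy <- function(x, ...) {
  cat("<patient_anatomy> ", x$patient_id, "\n", sep = "")
  print(round(x$landmarks, 3))
  if (!is.null(x$model_path)) cat("model: ", x$model_path, "\n", sep = "")
  disp <- attr(x, "snap_displacement_mm")
  if (!is.null(disp)) {
    cat("snapped to surface; displacements (mm): ",
        paste(sprintf("%s=%.3f", names(disp), disp), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a landmark annotation file
#'
#' Parses the sidecar annotation format: one `patient_id <id>` line and
#' exactly three `landmark <name> <x> <y> <z>` lines (millimetres),
#' whitespace-delimited, `#` starting a comment, order free. Parsing is
#' strict: unknown keys, missing or duplicated landmarks, and non-finite
#' coordinates are errors.
#'
#' @param path Path to the annotation file.
#' @return A [patient_anatomy()] object.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)

  pid <- NULL
  lm <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "patient_id") {
      if (length(tok) != 2L) {
        stop("malformed patient_id line: '", ln, "'", call. = FALSE)
      }
      if (!is.null(pid)) stop("duplicate patient_id line", call. = FALSE)
      pid <- tok[2]
    } else if (key == "landmark") {
      if (length(tok) != 5L) {
        stop("malformed landmark line (need name x y z): '", ln, "'",
             call. = FALSE)
      }
      nm <- tok[2]
      if (!nm %in% landmark_names()) {
        stop("unknown landmark name '", nm, "'; expected one of: ",
             paste(landmark_names(), collapse = ", "), call. = FALSE)
      }
      if (nm %in% names(lm)) {
        stop("duplicate landmark '", nm, "'", call. = FALSE)
      }
      xyz <- suppressWarnings(as.numeric(tok[3:5]))
      if (any(!is.finite(xyz))) {
        stop("non-finite coordinate for landmark '", nm, "': '", ln, "'",
             call. = FALSE)
      }
      lm[[nm]] <- xyz
    } else {
      stop("unknown key '", key, "' in annotation file", call. = FALSE)
    }
  }
  if (is.null(pid)) stop("annotation file lacks a patient_id line", call. = FALSE)
  missing <- setdiff(landmark_names(), names(lm))
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  patient_anatomy(pid, do.call(rbind, lm))
}

#' Write a landmark annotation file
#'
#' @param anatomy A [patient_anatomy()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(anatomy, path) {
  stopifnot(inherits(anatomy, "patient_anatomy"))
  lm <- anatomy$landmarks
  lines <- c(
    paste("patient_id", anatomy$patient_id),
    vapply(rownames(lm), function(nm) {
      sprintf("landmark %s %.9g %.9g %.9g", nm, lm[nm, 1], lm[nm, 2], lm[nm, 3])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Snap landmarks to the nearest vertex of a surface model
#'
#' Replaces each landmark position by the Euclidean-nearest vertex of the
#' triangulated surface. Snapping is optional and off by default in the
#' pipeline: measurements use authored landmark coordinates unless a model is
#' supplied and snapping requested.
#'
#' @param anatomy A [patient_anatomy()] object.
#' @param mesh An `stl_mesh` (see [read_stl()]) or a numeric n x 3 vertex
#'   matrix.
#' @return The snapped `patient_anatomy`, with attribute
#'   `snap_displacement_mm`: named vector of per-landmark displacements.
#' @export
snap_to_surface <- function(anatomy, mesh) {
  stopifnot(inherits(anatomy, "patient_anatomy"))
  v <- if (inherits(mesh, "stl_mesh")) mesh$vertices else as.matrix(mesh)
  if (is.null(v) || nrow(v) < 1L || ncol(v) != 3L) {
    stop("mesh has no vertices (need an n x 3 vertex set, n >= 1)",
         call. = FALSE)
  }
  lm <- anatomy$landmarks
  idx <- integer(3)
  disp <- numeric(3)
  for (i in seq_len(3)) {
    d2 <- (v[, 1] - lm[i, 1])^2 + (v[, 2] - lm[i, 2])^2 + (v[, 3] - lm[i, 3])^2
    idx[i] <- which.min(d2)
    disp[i] <- sqrt(d2[idx[i]])
  }
  if (anyDuplicated(idx) > 0L) {
    stop("degenerate annotation: two landmarks snap to the same mesh vertex",
         call. = FALSE)
  }
  snapped <- v[idx, , drop = FALSE]
  rownames(snapped) <- rownames(lm)
  out <- patient_anatomy(anatomy$patient_id, snapped, anatomy$model_path)
  names(disp) <- rownames(lm)
  attr(out, "snap_displacement_mm") <- disp
  out
}

#' Measure the two score distances of a patient anatomy
#'
#' Computes the straight-line Euclidean distances (mm) between the cranial
#' pulmonary vein landmark and, respectively, the sinus venosus defect rim
#' (`d_pv_svd`) and the azygos inferior rim (`d_pv_azygos`). The straight
#' chord — not a geodesic along the vessel wall — is the measurement
#' definition used throughout this package.
#'
#' @param anatomy A [patient_anatomy()] object.
#' @return An object of class `measurement_set`: list with `patient_id`,
#'   `d_pv_svd`, `d_pv_azygos` (both mm).
#' @export
#' @examples
#' lm <- rbind(
#'   PV_CRANIAL_SUPERIOR_RIM = c(0, 0, 0),
#'   SVD_SUPERIOR_RIM        = c(3, 4, 0),
#'   AZYGOS_INFERIOR_RIM     = c(0, 0, 10)
#' )
#' measure_anatomy(patient_anatomy("P001", lm))  # d_pv_svd 5, d_pv_azygos 10
measure_anatomy <- function(anatomy) {
  stopifnot(inherits(anatomy, "patient_anatomy"))
  lm <- anatomy$landmarks
  pv <- lm["PV_CRANIAL_SUPERIOR_RIM", ]
  d1 <- sqrt(sum((pv - lm["SVD_SUPERIOR_RIM", ])^2))
  d2 <- sqrt(sum((pv - lm["AZYGOS_INFERIOR_RIM", ])^2))
  if (d1 + d2 <= 0) {
    stop("degenerate anatomy: both score distances are zero", call. = FALSE)
  }
  structure(
    list(patient_id = anatomy$patient_id, d_pv_svd = d1, d_pv_azygos = d2),
    class = "measurement_set"
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %s: d_pv_svd = %.3f mm, d_pv_azygos = %.3f mm\n",
              x$patient_id, x$d_pv_svd, x$d_pv_azygos))
  invisible(x)
}

#' Measure a list of anatomies into a cohort table
#'
#' @param anatomies List of [patient_anatomy()] objects.
#' @return `data.frame` with columns `patient_id`, `d_pv_svd_mm`,
#'   `d_pv_azygos_mm`.
#' @export
measure_cohort <- function(anatomies) {
  stopifnot(is.list(anatomies), length(anatomies) >= 1L)
  ms <- lapply(anatomies, measure_anatomy)
  data.frame(
    patient_id = vapply(ms, `[[`, character(1), "patient_id"),
    d_pv_svd_mm = vapply(ms, `[[`, numeric(1), "d_pv_svd"),
    d_pv_azygos_mm = vapply(ms, `[[`, numeric(1), "d_pv_azygos"),
    stringsAsFactors = FALSE
  )
}
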