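# Empirical ROC analysis of the PAPVR ratio against the binary surgical
# outcome, Youden-optimal cutoff selection, and confusion counts.

# sentinel offset placed below the minimum / above the maximum observed ratio
.SENTINEL_OFFSET <- 0.01

#' Empirical ROC curve of PAPVR ratios against the surgical outcome
#'
#' Sweeps candidate thresholds and computes sensitivity (Warden correctly
#' called Warden) and specificity (patch correctly called patch) under the
#' classification rule `WARDEN iff ratio > threshold`. Candidate thresholds
#' are the midpoints between consecutive distinct sorted ratios, plus one
#' sentinel below the minimum and one above the maximum, so every achievable
#' confusion table is represented and classification at any chosen threshold
#' is unambiguous.
#'
#' The area under the curve is computed by the trapezoidal rule over
#' (1 - specificity, sensitivity); it equals the normalized Mann-Whitney U
#' statistic (the probability that a random Warden ratio exceeds a random
#' patch ratio, ties counted half).
#'
#' @param ratio Numeric vector of PAPVR ratios.
#' @param actual Procedure labels, same length; three-class labels are
#'   collapsed to the Warden-vs-patch dichotomy with [collapse_procedure()].
#' @return Object of class `papvr_roc`: list with `table` (data.frame of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_warden`,
#'   `n_patch`, `ratio`, `actual` (the collapsed labels), and the Youden
#'   selection `optimal` (see [optimal_cutoff()]).
#' @export
#' @examples
#' r <- roc_curve(c(0.5, 0.6, 0.8, 0.9),
#'                c("PATCH", "PATCH", "WARDEN", "WARDEN"))
#' r$auc                    # 1: perfect separation
#' optimal_cutoff(r)$cutoff # 0.7, the midpoint of the separating gap
roc_curve <- function(ratio, actual) {
  ratio <- as.numeric(ratio)
  if (length(ratio) != length(actual)) {
    stop("`ratio` and `actual` must have equal length", call. = FALSE)
  }
  if (length(ratio) < 2L) stop("need at least two patients", call. = FALSE)
  if (any(!is.finite(ratio))) stop("ratios must be finite", call. = FALSE)
  lab <- collapse_procedure(actual)
  is_w <- lab == "WARDEN"
  if (!any(is_w)) stop("no WARDEN patients in cohort", call. = FALSE)
  if (all(is_w)) stop("no PATCH patients in cohort", call. = FALSE)

  u <- sort(unique(ratio))
  thresholds <- c(u[1] - .SENTINEL_OFFSET,
                  if (length(u) > 1L) (u[-length(u)] + u[-1]) / 2,
                  u[length(u)] + .SENTINEL_OFFSET)
  sens <- vapply(thresholds, function(t) mean(ratio[is_w] > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(ratio[!is_w] <= t), numeric(1))

  # trapezoid over the ROC points ordered by increasing false-positive rate
  fpr <- rev(1 - spec)  # thresholds descending -> FPR ascending 0..1
  tpr <- rev(sens)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  out <- structure(
    list(
      table = data.frame(threshold = thresholds, sensitivity = sens,
                         specificity = spec),
      auc = auc,
      n_warden = sum(is_w),
      n_patch = sum(!is_w),
      ratio = ratio,
      actual = lab,
      optimal = NULL
    ),
    class = "papvr_roc"
  )
  out$optimal <- .youden_select(out)
  out
}

# Youden selection over a papvr_roc threshold table
.youden_select <- function(roc) {
  tab <- roc$table
  j <- tab$sensitivity + tab$specificity - 1
  degenerate <- max(j) <= 0
  if (degenerate) {
    # no threshold discriminates: report the lowest sentinel
    pick <- 1L
  } else {
    best <- which(j == max(j))
    best <- best[tab$specificity[best] == max(tab$specificity[best])]
    pick <- best[which.min(tab$threshold[best])]
  }
  list(cutoff = tab$threshold[pick],
       sensitivity = tab$sensitivity[pick],
       specificity = tab$specificity[pick],
       youden = j[pick],
       degenerate = degenerate)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Selects the threshold maximizing Youden's J = sensitivity + specificity
#' - 1. Ties are broken in favour of higher specificity, then the lower
#' threshold: the clinical cost asymmetry argues against over-calling a
#' Warden procedure (prosthetic conduit and anticoagulation in adults), so
#' among equally informative thresholds the more Warden-conservative one is
#' preferred. If no threshold discriminates at all (maximum J is 0) a
#' degeneracy warning is raised and the lowest sentinel threshold returned.
#'
#' @param roc A `papvr_roc` from [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `degenerate`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "papvr_roc"))
  sel <- .youden_select(roc)
  if (sel$degenerate) {
    warning("degenerate ROC: no threshold discriminates the groups ",
            "(max Youden J = 0); returning the lowest sentinel threshold",
            call. = FALSE)
  }
  sel
}

#' Confusion counts at a fixed cutoff
#'
#' Counts the 2x2 contingency of predicted (ratio > cutoff -> Warden)
#' against actual procedure, with the Warden class as positive.
#'
#' @param ratio Numeric vector of PAPVR ratios.
#' @param actual Procedure labels (three-class labels are collapsed).
#' @param cutoff Decision threshold in (0, 1).
#' @return Object of class `papvr_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `cutoff`. Sensitivity or
#'   specificity is `NaN` when the corresponding class is absent.
#' @export
#' @examples
#' confusion_at(c(0.99, 0.82, 0.88), rep("WARDEN", 3), 0.68)  # TP = 3
confusion_at <- function(ratio, actual, cutoff) {
  ratio <- as.numeric(ratio)
  if (length(ratio) == 0L) stop("empty input", call. = FALSE)
  if (length(ratio) != length(actual)) {
    stop("`ratio` and `actual` must have equal length", call. = FALSE)
  }
  lab <- collapse_procedure(actual)
  pred <- classify_procedure(ratio, cutoff)
  tp <- sum(pred == "WARDEN" & lab == "WARDEN")
  fp <- sum(pred == "WARDEN" & lab == "PATCH")
  tn <- sum(pred == "PATCH" & lab == "PATCH")
  fn <- sum(pred == "PATCH" & lab == "WARDEN")
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         cutoff = cutoff),
    class = "papvr_confusion"
  )
}

#' @export
print.papvr_roc <- function(x, ...) {
  cat(sprintf("<papvr_roc> %d WARDEN vs %d PATCH, AUC = %.3f\n",
              x$n_warden, x$n_patch, x$auc))
  cat(sprintf("Youden-optimal cutoff %.2f (sensitivity %.2f, specificity %.2f)\n",
              x$optimal$cutoff, x$optimal$sensitivity, x$optimal$specificity))
  invisible(x)
}

#' @export
print.papvr_confusion <- function(x, ...) {
  cat(sprintf("<papvr_confusion> cutoff %.2f\n", x$cutoff))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("WARDEN", "PATCH"),
                              actual = c("WARDEN", "PATCH")))
  print(m)
  cat(sprintf("sensitivity %.2f, specificity %.2f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}
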