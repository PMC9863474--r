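# shared fixtures built in code

# anatomy with landmarks at given coordinates (rows: PV, SVD, AZY)
make_anatomy <- function(pv = c(0, 0, 0), svd = c(0, 0, 10),
                         azy = c(0, 0, -15), id = "T001") {
  patient_anatomy(id, rbind(
    PV_CRANIAL_SUPERIOR_RIM = pv,
    SVD_SUPERIOR_RIM = svd,
    AZYGOS_INFERIOR_RIM = azy
  ))
}

# random 3x3 rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# write a landmark annotation file; `drop`/`dup` manipulate records for
# error-path tests
write_lmk_file <- function(path, id = "T001",
                           coords = list(PV_CRANIAL_SUPERIOR_RIM = c(0, 0, 0),
                                         SVD_SUPERIOR_RIM = c(0, 0, 10),
                                         AZYGOS_INFERIOR_RIM = c(0, 0, 25)),
                           drop = NULL, dup = NULL, extra_lines = NULL) {
  lines <- paste("patient_id", id)
  for (nm in setdiff(names(coords), drop)) {
    lines <- c(lines, paste("landmark", nm,
                            paste(coords[[nm]], collapse = " ")))
  }
  if (!is.null(dup)) {
    lines <- c(lines, paste("landmark", dup,
                            paste(coords[[dup]], collapse = " ")))
  }
  lines <- c(lines, extra_lines)
  writeLines(lines, path)
  path
}

# exhaustive threshold sweep: independent oracle for Youden selection.
# Scans every threshold between consecutive order statistics plus sentinels,
# computing sensitivity/specificity from first principles.
brute_force_cutoff <- function(ratio, actual) {
  is_w <- actual == "WARDEN"
  u <- sort(unique(ratio))
  cand <- c(u[1] - 0.01,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 0.01)
  sens <- sapply(cand, function(t) sum(ratio[is_w] > t) / sum(is_w))
  spec <- sapply(cand, function(t) sum(ratio[!is_w] <= t) / sum(!is_w))
  j <- sens + spec - 1
  if (max(j) <= 0) {
    # no discriminating threshold: documented convention is the low sentinel
    pick <- 1L
  } else {
    best <- which(j == max(j))
    best <- best[spec[best] == max(spec[best])]
    pick <- best[which.min(cand[best])]
  }
  list(cutoff = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick], youden = j[pick])
}

# Mann-Whitney probability that a Warden ratio exceeds a patch ratio,
# ties counted half
mann_whitney_auc <- function(ratio, actual) {
  w <- ratio[actual == "WARDEN"]
  p <- ratio[actual == "PATCH"]
  cmp <- outer(w, p, ">") + 0.5 * outer(w, p, "==")
  mean(cmp)
}
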