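#' Sign-aware confusion counts over taxon pairs
#'
#' Scores an estimated precision (or signed score) matrix against the true
#' precision matrix over the p(p-1)/2 unordered taxon pairs. A pair is a true
#' positive only when the truth is nonzero, the estimate is nonzero, AND the
#' two share the same sign. Each pair receives exactly one label, so the four
#' counts always partition the pairs; a nonzero estimate with the wrong sign
#' at a true edge is counted by the `wrong_sign` precedence rule: `"fp"`
#' (default: a wrong claim was made) or `"fn"` (the true edge was missed).
#'
#' @param omega_hat p x p symmetric estimate.
#' @param omega_true p x p symmetric truth.
#' @param wrong_sign label for a wrong-signed detection at a true edge.
#' @param tol absolute threshold below which an entry counts as zero.
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
signed_confusion <- function(omega_hat, omega_true,
                             wrong_sign = c("fp", "fn"), tol = 1e-8) {
  wrong_sign <- match.arg(wrong_sign)
  if (!all(dim(omega_hat) == dim(omega_true)))
    stop("dimension mismatch between estimate and truth")
  ut <- upper.tri(omega_true)
  e <- omega_hat[ut]; t_ <- omega_true[ut]
  est_nz <- abs(e) > tol
  tru_nz <- abs(t_) > tol
  same_sign <- sign(e) == sign(t_)
  tp <- sum(tru_nz & est_nz & same_sign)
  tn <- sum(!tru_nz & !est_nz)
  wrong <- sum(tru_nz & est_nz & !same_sign)
  fp <- sum(!tru_nz & est_nz) + if (wrong_sign == "fp") wrong else 0L
  fn <- sum(tru_nz & !est_nz) + if (wrong_sign == "fn") wrong else 0L
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); defined as 0 when
#' any factor of the denominator is zero. Ranges over [-1, 1], 1 being
#' perfect recovery; well suited to the heavy class imbalance of sparse
#' networks.
#'
#' @param c a `confusion_counts` (or list with tp, tn, fp, fn).
#' @return MCC in [-1, 1].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# internal: confusion-derived ROC point
roc_point <- function(cc) {
  tpr <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
  fpr <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else 0
  c(fpr = fpr, tpr = tpr)
}

#' ROC curve and AUC for network recovery
#'
#' Two modes. Path mode (`estimates` is a list of precision matrices, one per
#' penalty): each matrix yields one confusion count and so one ROC point,
#' compared sign-aware against `omega_true`. Score mode (`estimates` is a
#' single symmetric score matrix, e.g. correlations): every unique absolute
#' off-diagonal value defines a threshold; entries below it are zeroed and the
#' surviving signed entries are compared against the sign of the true partial
#' correlation (the negated off-diagonal precision sign). The curve is
#' augmented with (0,0) and (1,1) and the AUC computed by trapezoid.
#'
#' @param estimates list of p x p matrices (path mode) or one p x p score
#'   matrix (score mode).
#' @param omega_true true precision matrix.
#' @param sign_aware require sign agreement for a true positive (the default);
#'   with FALSE only the sparsity pattern is compared (rank-only scoring).
#' @param wrong_sign passed to [signed_confusion].
#' @return list with `points` (data.frame fpr, tpr ordered along the curve)
#'   and `auc`; `flagged` is TRUE when truth has no edges (AUC undefined, NA).
#' @export
roc_auc_path <- function(estimates, omega_true, sign_aware = TRUE,
                         wrong_sign = "fp") {
  ut <- upper.tri(omega_true)
  if (!any(abs(omega_true[ut]) > 1e-8))
    return(list(points = NULL, auc = NA_real_, flagged = TRUE))
  truth <- if (sign_aware) omega_true else abs(omega_true)
  if (is.matrix(estimates)) {
    # score mode: compare score signs against true partial-correlation signs
    sc <- estimates
    diag(sc) <- 0
    truth_pc <- -omega_true
    diag(truth_pc) <- 1
    tr <- if (sign_aware) truth_pc else abs(truth_pc)
    thr <- sort(unique(abs(sc[ut])))
    mats <- lapply(thr, function(t0) sc * (abs(sc) >= t0))
    pts <- t(vapply(mats, function(m) roc_point(
      signed_confusion(if (sign_aware) m else abs(m), tr,
                       wrong_sign = wrong_sign)), numeric(2)))
  } else {
    pts <- t(vapply(estimates, function(m) roc_point(
      signed_confusion(if (sign_aware) m else abs(m), truth,
                       wrong_sign = wrong_sign)), numeric(2)))
  }
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
  auc <- sum(diff(pts[, 1L]) * (pts[-1L, 2L] + pts[-nrow(pts), 2L]) / 2)
  list(points = data.frame(fpr = pts[, 1L], tpr = pts[, 2L]),
       auc = auc, flagged = FALSE)
}

#' Area under the precision-recall curve for edge confidences
#'
#' Ranks taxon pairs by confidence (e.g. StARS edge stabilities, which are
#' non-negative, so no sign enters) and walks the unique confidence values as
#' thresholds, computing precision TP/(TP+FP) and recall TP/(TP+FN) on the
#' sparsity pattern. The area is the trapezoid over recall, with the curve
#' anchored at recall 0 (carrying the first point's precision). All-equal
#' confidences give a single operating point and an AUPR equal to the edge
#' prevalence (the constant-classifier limit).
#'
#' @param confidence symmetric p x p non-negative edge scores.
#' @param omega_true true precision matrix (only its sparsity pattern enters).
#' @return list with `points` (recall, precision) and `aupr`; `flagged` TRUE
#'   when truth has no edges (NA area).
#' @export
aupr <- function(confidence, omega_true) {
  ut <- upper.tri(omega_true)
  truth <- abs(omega_true[ut]) > 1e-8
  npos <- sum(truth)
  if (npos == 0L) return(list(points = NULL, aupr = NA_real_, flagged = TRUE))
  sc <- abs(confidence[ut])
  thr <- sort(unique(sc), decreasing = TRUE)
  pr <- t(vapply(thr, function(t0) {
    det <- sc >= t0
    tp <- sum(det & truth)
    c(recall = tp / npos,
      precision = if (any(det)) tp / sum(det) else 1)
  }, numeric(2)))
  pr <- pr[order(pr[, "recall"]), , drop = FALSE]
  pts <- rbind(c(0, pr[1L, "precision"]), pr)
  area <- sum(diff(pts[, 1L]) * (pts[-1L, 2L] + pts[-nrow(pts), 2L]) / 2)
  list(points = data.frame(recall = pts[, 1L], precision = pts[, 2L]),
       aupr = area, flagged = FALSE)
}

#' Pearson-correlation baseline scores
#'
#' The naive comparator: the full matrix of pairwise Pearson correlations of
#' the normalized abundances, used as edge scores in [roc_auc_path] / [aupr]
#' or hard-thresholded with [oracle_threshold]. Constant columns get zero
#' correlations with a warning.
#'
#' @param Z n x p matrix (n >= 3).
#' @return symmetric p x p correlation score matrix.
#' @export
pearson_baseline <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 3) stop("need at least 3 samples")
  const <- apply(Z, 2L, function(x) sd(x) == 0 || !is.finite(sd(x)))
  C <- suppressWarnings(cor(Z))
  if (any(const)) {
    warning("constant column(s): correlations set to 0 for ",
            paste(colnames(Z)[const], collapse = ", "))
  }
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' Keep only the k strongest edges of a score matrix
#'
#' Oracle-style thresholding used to benchmark correlation methods: retains
#' the `k` largest absolute off-diagonal scores (as many edges as the true
#' network has) and zeroes the rest.
#'
#' @param scores symmetric score matrix.
#' @param k number of edges to keep.
#' @return sparse score matrix (zero diagonal).
#' @export
oracle_threshold <- function(scores, k) {
  p <- nrow(scores)
  ut <- upper.tri(scores)
  v <- abs(scores[ut])
  out <- matrix(0, p, p, dimnames = dimnames(scores))
  if (k > 0) {
    thr <- sort(v, decreasing = TRUE)[min(k, length(v))]
    keep <- ut & abs(scores) >= thr
    out[keep] <- scores[keep]
    out <- out + t(out)
  }
  out
}
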