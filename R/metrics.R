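# Residue- and protein-level evaluation: dataset-wide threshold calibration,
# ROC/precision-recall areas, confusion-matrix metrics, disorder-content
# error/correlation and fully-disordered-protein classification.

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' disordered residue scores above a randomly chosen ordered one, with ties
#' counted 1/2. Invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric vector of propensities.
#' @param labels Integer 0/1 vector of the same length.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  npos <- as.numeric(sum(labels == 1L))
  nneg <- as.numeric(sum(labels == 0L))
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: need at least one positive and one negative label",
         call. = FALSE)
  r <- rank(scores)   # average ranks give the 1/2 tie convention
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Precision-recall area under the curve
#'
#' Average-precision formulation without interpolation: the sum over
#' descending unique score thresholds of precision times the recall
#' increment. Equals the mean of precision at each positive's rank when the
#' scores are tie-free.
#'
#' @param scores Numeric vector of propensities.
#' @param labels Integer 0/1 vector; at least one positive required.
#' @return AUPRC in \[0,1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  npos <- sum(labels == 1L)
  if (npos == 0L)
    stop("AUPRC undefined: no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # evaluate only at the last index of each tied score block
  last <- c(which(diff(s) != 0), length(s))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion counts for binary disorder predictions
#'
#' @param pred Integer 0/1 predictions.
#' @param actual Integer 0/1 labels.
#' @return List with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, actual) {
  pred <- as.integer(pred); actual <- as.integer(actual)
  if (length(pred) != length(actual))
    stop("pred and actual differ in length", call. = FALSE)
  list(tp = sum(pred == 1L & actual == 1L),
       tn = sum(pred == 0L & actual == 0L),
       fp = sum(pred == 1L & actual == 0L),
       fn = sum(pred == 0L & actual == 1L))
}

#' Binary classification metrics from confusion counts
#'
#' Computes F1 = 2TP/(2TP+FP+FN), sensitivity = TP/(TP+FN) and the Matthews
#' correlation coefficient. A zero denominator yields 0 for that metric with
#' `degenerate = TRUE`, so dataset-level aggregation never aborts.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see [confusion_counts()]).
#' @return List with `mcc`, `f1`, `sensitivity`, `degenerate`.
#' @export
binary_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  f1_den <- 2 * tp + fp + fn
  f1 <- if (f1_den > 0) 2 * tp / f1_den else { degenerate <- TRUE; 0 }
  sens <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else { degenerate <- TRUE; 0 }
  list(mcc = mcc, f1 = f1, sensitivity = sens, degenerate = degenerate)
}

#' Calibrate a binary cut-off to the native disorder count
#'
#' Finds the threshold `t` such that the number of pooled residues scoring
#' strictly above `t` best matches the number of natively disordered residues
#' over the same pool. Candidates are the observed scores plus 0; ties in the
#' objective are broken toward fewer predicted disordered residues, then
#' toward the smaller threshold. This calibration puts all methods on the
#' same footing before confusion-matrix metrics are computed.
#'
#' @param profiles Named list of [score_profile] objects.
#' @param references Named list of [ref_entry] objects; profiles are matched
#'   to references by identifier and unmatched profiles are an error.
#' @return List of class `calibrated_threshold` with fields `method`,
#'   `threshold`, `target_count`, `achieved_count`.
#' @export
calibrate_threshold <- function(profiles, references) {
  if (!length(profiles)) stop("empty profile pool", call. = FALSE)
  ids <- vapply(profiles, `[[`, "", "id")
  missing <- setdiff(ids, names(references))
  if (length(missing))
    stop(sprintf("profile(s) with no matching reference: %s",
                 paste(utils::head(missing, 3), collapse = ",")), call. = FALSE)
  scores <- unlist(lapply(profiles, `[[`, "scores"), use.names = FALSE)
  target <- sum(vapply(ids, function(i) sum(references[[i]]$disorder), 0L))
  if (!length(scores)) stop("empty score pool", call. = FALSE)
  cand <- sort(unique(c(0, scores)))
  # number of scores strictly above each candidate
  ss <- sort(scores)
  above <- length(ss) - findInterval(cand, ss)
  obj <- abs(above - target)
  keep <- which(obj == min(obj))
  keep <- keep[above[keep] == min(above[keep])]   # fewer predicted wins ties
  pick <- keep[1]                                 # then smallest threshold
  structure(list(method = profiles[[1]]$method, threshold = cand[pick],
                 target_count = as.integer(target),
                 achieved_count = as.integer(above[pick])),
            class = "calibrated_threshold")
}

#' @export
print.calibrated_threshold <- function(x, ...) {
  cat(sprintf("<calibrated_threshold> %s  t=%.4g  target=%d  achieved=%d\n",
              x$method, x$threshold, x$target_count, x$achieved_count))
  invisible(x)
}

#' Binarize a score profile at a calibrated threshold
#'
#' Residues with propensity strictly above the cut-off are called disordered.
#'
#' @param profile A [score_profile].
#' @param t A `calibrated_threshold` or a bare numeric cut-off.
#' @return The profile with its `binary` field filled.
#' @export
binarize <- function(profile, t) {
  thr <- if (inherits(t, "calibrated_threshold")) t$threshold else as.numeric(t)
  profile$binary <- as.integer(profile$scores > thr)
  profile
}

#' Disorder content of a label or binary-call series
#'
#' @param x Integer 0/1 vector of length >= 1.
#' @return Fraction of 1s, in \[0,1\].
#' @export
disorder_content <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  mean(as.integer(x))
}

#' Mean absolute error between predicted and native disorder content
#'
#' @param pred,native Numeric vectors of per-protein content values.
#' @return Mean absolute difference.
#' @export
content_mae <- function(pred, native) {
  if (length(pred) != length(native) || !length(pred))
    stop("content vectors must have equal positive length", call. = FALSE)
  mean(abs(pred - native))
}

#' Spearman correlation between predicted and native disorder content
#'
#' Rank correlation with average ranks for ties; equals the classical
#' 1 - 6*sum(d^2)/(n(n^2-1)) formula on tie-free inputs.
#'
#' @param pred,native Numeric vectors of per-protein content values (n >= 2).
#' @return Correlation in \[-1,1\].
#' @export
content_scc <- function(pred, native) {
  if (length(pred) != length(native) || length(pred) < 2L)
    stop("content vectors must have equal length >= 2", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(native) == 0)
    stop("SCC undefined: zero variance in a content vector", call. = FALSE)
  stats::cor(pred, native, method = "spearman")
}

#' Protein-level evaluation of fully disordered protein prediction
#'
#' A protein is natively fully disordered when its native content is strictly
#' above the cut-off, and predicted fully disordered when its predicted
#' content is strictly above the same cut-off. F1 and sensitivity are
#' computed from the resulting protein-level confusion counts.
#'
#' @param pred_content,native_content Per-protein content vectors in \[0,1\].
#' @param cutoff Content cut-off, conventionally 0.99, 0.90 or 0.80.
#' @return List with `f1`, `sensitivity`, `counts`.
#' @export
fdp_eval <- function(pred_content, native_content, cutoff) {
  if (length(pred_content) != length(native_content))
    stop("content vectors differ in length", call. = FALSE)
  native_fdp <- as.integer(native_content > cutoff)
  if (sum(native_fdp) == 0L)
    stop("FDP evaluation undefined: no natively fully disordered proteins",
         call. = FALSE)
  pred_fdp <- as.integer(pred_content > cutoff)
  cc <- confusion_counts(pred_fdp, native_fdp)
  bm <- binary_metrics(cc)
  list(f1 = bm$f1, sensitivity = bm$sensitivity, counts = cc)
}

#' Pooled residue-level evaluation of one method on one protein set
#'
#' Pools the residues of all matched proteins (micro-average), computes AUC
#' and AUPRC from the propensities and MCC/F1/sensitivity from binary calls
#' at the supplied threshold, and reports the fraction of references covered
#' by a profile.
#'
#' @param profiles Named list of [score_profile] objects for one method.
#' @param references Named list of [ref_entry] objects defining the protein
#'   set; references without a profile reduce coverage but are not an error.
#' @param threshold A `calibrated_threshold` or numeric cut-off used for the
#'   binary metrics.
#' @return List of class `eval_record`.
#' @export
evaluate_method <- function(profiles, references, threshold) {
  ids <- intersect(names(references), names(profiles))
  if (!length(ids)) stop("no reference protein has a profile", call. = FALSE)
  scores <- unlist(lapply(ids, function(i) profiles[[i]]$scores), use.names = FALSE)
  labels <- unlist(lapply(ids, function(i) references[[i]]$disorder), use.names = FALSE)
  if (length(scores) != length(labels))
    stop("profile/reference length mismatch within the evaluated set", call. = FALSE)
  thr <- if (inherits(threshold, "calibrated_threshold")) threshold$threshold
         else as.numeric(threshold)
  bm <- binary_metrics(confusion_counts(as.integer(scores > thr), labels))
  structure(list(method = profiles[[ids[1]]]$method,
                 n_proteins = length(ids),
                 coverage = length(ids) / length(references),
                 threshold = thr,
                 auc = roc_auc(scores, labels),
                 auprc = pr_auc(scores, labels),
                 mcc = bm$mcc, f1 = bm$f1, sensitivity = bm$sensitivity),
            class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat(sprintf("<eval_record> %s  n=%d  cov=%.0f%%  AUC=%.3f  AUPRC=%.3f  MCC=%.3f  F1=%.3f\n",
              x$method, x$n_proteins, 100 * x$coverage, x$auc, x$auprc, x$mcc, x$f1))
  invisible(x)
}

#' Per-protein ROC AUC for a method
#'
#' Proteins whose labels are single-class (for instance fully disordered
#' proteins, which have no ordered residues) have undefined AUC and are
#' returned as `NA`.
#'
#' @param profiles Named list of [score_profile] objects.
#' @param references Named list of [ref_entry] objects.
#' @return Named numeric vector of AUCs over references with a profile.
#' @export
per_protein_auc <- function(profiles, references) {
  ids <- intersect(names(references), names(profiles))
  vapply(ids, function(i) {
    y <- references[[i]]$disorder
    if (sum(y) == 0L || sum(y) == length(y)) return(NA_real_)
    roc_auc(profiles[[i]]$scores, y)
  }, 0)
}
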