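# Sequence-derived markers that identify proteins where the structure-derived
# disorder predictor is competitive with dedicated disorder predictors:
# marker computation, the competitive split, distribution comparison and the
# below-median selection rule.

#' Compute the eight per-protein markers
#'
#' From the reference entry and binary (thresholded) profiles of disorder,
#' protein-binding and coiled-coil predictions, computes: sequence length;
#' putative disorder content; putative binding content; number and maximal
#' length of putative IDRs (runs of at least 4 consecutive
#' predicted-disordered residues); putative coiled-coil content; distance of
#' the putative IDRs to the closest terminus (minimum over IDR residues of
#' min(i-1, L-i); sentinel L+1 when there is no putative IDR); and a
#' composite score, the sum of terminus distances over all
#' predicted-disordered residues divided by the sequence length. Terminal
#' residues have distance 0, so low composite values flag proteins whose
#' disorder is scarce and/or terminal.
#'
#' @param entry A [ref_entry].
#' @param disorder_profile [score_profile] with binary disorder calls.
#' @param binding_profile [score_profile] with binary binding-region calls.
#' @param coil_profile [score_profile] with binary coiled-coil calls.
#' @param min_idr_len Minimum putative IDR length, default 4.
#' @return One-row data frame with the eight marker columns plus `id`.
#' @export
compute_markers <- function(entry, disorder_profile, binding_profile,
                            coil_profile, min_idr_len = 4L) {
  L <- nchar(entry$sequence)
  for (p in list(disorder_profile, binding_profile, coil_profile)) {
    if (is.null(p$binary))
      stop(sprintf("profile '%s' [%s] lacks binary calls", p$id, p$method),
           call. = FALSE)
    if (length(p$binary) != L)
      stop(sprintf("profile '%s' [%s] length %d does not match sequence length %d",
                   p$id, p$method, length(p$binary), L), call. = FALSE)
  }
  dis <- disorder_profile$binary
  seg <- extract_idrs(dis, min_len = min_idr_len)
  term_dist <- pmin(seq_len(L) - 1L, L - seq_len(L))
  idr_res <- unlist(lapply(seq_len(nrow(seg)),
                           function(k) seg$start[k]:seg$end[k]), use.names = FALSE)
  data.frame(
    id = entry$id,
    seq_length = L,
    putative_content = mean(dis),
    binding_content = mean(binding_profile$binary),
    n_putative_idrs = nrow(seg),
    max_idr_len = if (nrow(seg)) max(seg$length) else 0L,
    coil_content = mean(coil_profile$binary),
    min_terminus_distance = if (length(idr_res)) min(term_dist[idr_res]) else L + 1L,
    composite = sum(term_dist[dis == 1L]) / L)
}

#' Marker table for a cohort
#'
#' @param entries Named list of [ref_entry] objects.
#' @param disorder_profiles,binding_profiles,coil_profiles Named lists of
#'   binary [score_profile] objects keyed by protein id.
#' @param min_idr_len Minimum putative IDR length, default 4.
#' @return Data frame, one row per protein present in all four inputs.
#' @export
marker_table <- function(entries, disorder_profiles, binding_profiles,
                         coil_profiles, min_idr_len = 4L) {
  ids <- Reduce(intersect, list(names(entries), names(disorder_profiles),
                                names(binding_profiles), names(coil_profiles)))
  do.call(rbind, lapply(ids, function(i) {
    compute_markers(entries[[i]], disorder_profiles[[i]], binding_profiles[[i]],
                    coil_profiles[[i]], min_idr_len)
  }))
}

#' Split proteins into AF2-competitive and the rest
#'
#' A protein is competitive when the structure-derived predictor's
#' per-protein AUC (i) strictly exceeds `auc_floor` (instantiated with the
#' best disorder predictor's dataset-level AUC) and (ii) is not below the
#' lower bound of the 95% normal-approximation confidence interval of that
#' protein's AUCs across the panel of disorder predictors
#' (mean - 1.96 sd / sqrt(k)). Proteins with a missing or undefined AUC are
#' excluded and reported in `excluded`.
#'
#' @param af2_auc Named numeric vector of per-protein AUCs for the
#'   structure-derived predictor (`NA` = undefined).
#' @param predictor_aucs Numeric matrix of per-protein AUCs, rows named by
#'   protein id, one column per disorder predictor.
#' @param auc_floor AUC floor, e.g. the top predictor's dataset-level AUC.
#' @return Object of class `competitive_split` with fields `competitive`,
#'   `rest`, `excluded`, `auc_floor`.
#' @export
competitive_split <- function(af2_auc, predictor_aucs, auc_floor) {
  ids <- intersect(names(af2_auc), rownames(predictor_aucs))
  ok <- ids[!is.na(af2_auc[ids]) &
              apply(!is.na(predictor_aucs[ids, , drop = FALSE]), 1, any)]
  excluded <- setdiff(union(names(af2_auc), rownames(predictor_aucs)), ok)
  k <- ncol(predictor_aucs)
  comp <- vapply(ok, function(i) {
    x <- af2_auc[[i]]
    panel <- predictor_aucs[i, ]
    panel <- panel[!is.na(panel)]
    lower <- mean(panel) - 1.96 * stats::sd(panel) / sqrt(length(panel))
    x > auc_floor && x >= lower
  }, TRUE)
  structure(list(competitive = ok[comp], rest = ok[!comp],
                 excluded = excluded, auc_floor = auc_floor),
            class = "competitive_split")
}

#' @export
print.competitive_split <- function(x, ...) {
  cat(sprintf("<competitive_split> competitive=%d  rest=%d  excluded=%d  floor=%.3f\n",
              length(x$competitive), length(x$rest), length(x$excluded), x$auc_floor))
  invisible(x)
}

#' Compare marker distributions between the two protein groups
#'
#' Two-sided Wilcoxon rank-sum test per marker (the markers are heavily
#' non-normal counts and fractions). A marker constant across both groups
#' has no distributional difference to test and is reported with p = 1 and
#' `degenerate = TRUE`.
#'
#' @param split A `competitive_split`.
#' @param markers Marker data frame from [marker_table()].
#' @param alpha Significance level, default 0.05.
#' @return Data frame with columns `marker`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
compare_marker_distributions <- function(split, markers, alpha = 0.05) {
  if (!length(split$competitive) || !length(split$rest))
    stop("both groups must be non-empty", call. = FALSE)
  cols <- setdiff(names(markers), "id")
  g1 <- markers[markers$id %in% split$competitive, , drop = FALSE]
  g2 <- markers[markers$id %in% split$rest, , drop = FALSE]
  rows <- lapply(cols, function(m) {
    x <- g1[[m]]; y <- g2[[m]]
    if (length(unique(c(x, y))) == 1L)
      return(data.frame(marker = m, p_value = 1, significant = FALSE,
                        degenerate = TRUE))
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(marker = m, p_value = p, significant = p < alpha,
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Below-median marker selection
#'
#' Selects the proteins whose values on every active marker are strictly
#' below the corresponding median computed on the competitive group — the
#' rule that isolates proteins for which the structure-derived predictor is
#' expected to excel.
#'
#' @param markers Marker data frame from [marker_table()].
#' @param medians Named numeric vector of per-marker medians (typically from
#'   the competitive group).
#' @param active Character vector of marker names to apply.
#' @return Character vector of selected protein ids.
#' @export
marker_select <- function(markers, medians, active) {
  missing <- setdiff(active, names(markers))
  if (length(missing))
    stop(sprintf("unknown marker(s): %s", paste(missing, collapse = ",")),
         call. = FALSE)
  keep <- rep(TRUE, nrow(markers))
  for (m in active) keep <- keep & markers[[m]] < medians[[m]]
  markers$id[keep]
}
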