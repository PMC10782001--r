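# Orchestration: run the full evaluation over a cohort and a panel of
# methods, attach resampling verdicts, and emit TSV + JSON report tables.

fmt_verdict_cell <- function(value, symbols) {
  if (!length(symbols)) return(sprintf("%.3f", value))
  sprintf("%.3f %s", value, paste(symbols, collapse = "|"))
}

# Verdict symbols of `method` against each method in `compare_to`, from a
# subset-by-method series matrix. Self-comparison renders as "".
verdict_symbols <- function(series, method, compare_to, higher_better = TRUE) {
  vapply(compare_to, function(ref) {
    if (ref == method) return("")
    if (!(method %in% colnames(series)) || !(ref %in% colnames(series)))
      return(NA_character_)
    tryCatch(paired_verdict(series[, ref], series[, method],
                            higher_better = higher_better)$symbol,
             error = function(e) NA_character_)
  }, "")
}

#' Run the full comparative benchmark
#'
#' Calibrates every method's binary cut-off to the native disorder count,
#' then produces: the dataset summary; the residue-level table (threshold,
#' coverage, AUC, AUPRC, MCC, F1); the per-IDR-type AUC table over the
#' shortIDR/longIDR/bindingIDR/non-terminusIDR subsets; the protein-level
#' disorder-content table (MAE, SCC); and the fully-disordered-protein table
#' (F1, sensitivity at the 0.99/0.90/0.80 content cut-offs). When
#' `compare_to` is non-empty each metric cell carries resampling verdicts
#' (`+`/`-`/`=`, reference method significantly better / worse / not
#' different) from 20 disjoint 5% subsets for residue-level and content
#' metrics and 20 sampled 20% subsets for the sparse FDP evaluation.
#'
#' @param entries Named list of [ref_entry] objects.
#' @param methods Named list: method name -> named list of [score_profile]
#'   objects keyed by protein id.
#' @param seed Integer seed driving the subset sampling.
#' @param compare_to Character vector of reference methods for verdicts;
#'   defaults to the method with the highest dataset-level AUC.
#' @param fdp_cutoffs Content cut-offs for the FDP evaluation.
#' @param n_subsets Number of resampling subsets, default 20.
#' @param verdicts Set `FALSE` to skip significance testing.
#' @return Object of class `benchmark_bundle`: a list of data frames
#'   (`summary`, `residue`, `idr_auc`, `content`, `fdp`) plus `thresholds`
#'   and a `log` of seeds and exclusions.
#' @export
run_benchmark <- function(entries, methods, seed = 1L, compare_to = NULL,
                          fdp_cutoffs = c(0.99, 0.90, 0.80),
                          n_subsets = 20L, verdicts = TRUE) {
  stopifnot(length(entries) >= 1L, length(methods) >= 1L,
            !is.null(names(methods)))
  membership <- build_datasets(entries)
  summary_tab <- dataset_summary(membership, entries)

  thresholds <- lapply(names(methods), function(m) {
    covered <- methods[[m]][intersect(names(methods[[m]]), names(entries))]
    calibrate_threshold(covered, entries)
  })
  names(thresholds) <- names(methods)

  records <- lapply(names(methods), function(m)
    evaluate_method(methods[[m]], entries, thresholds[[m]]))
  names(records) <- names(methods)
  aucs <- vapply(records, `[[`, 0, "auc")
  if (is.null(compare_to) && verdicts)
    compare_to <- names(which.max(aucs))

  native_content <- vapply(entries, function(e) disorder_content(e$disorder), 0)
  pred_content <- lapply(names(methods), function(m) {
    ids <- intersect(names(methods[[m]]), names(entries))
    vapply(ids, function(i)
      disorder_content(binarize(methods[[m]][[i]], thresholds[[m]])$binary), 0)
  })
  names(pred_content) <- names(methods)

  pooled_metric <- function(m, ids, metric) {
    ids <- intersect(ids, names(methods[[m]]))
    if (!length(ids)) stop("no coverage")
    s <- unlist(lapply(ids, function(i) methods[[m]][[i]]$scores), use.names = FALSE)
    y <- unlist(lapply(ids, function(i) entries[[i]]$disorder), use.names = FALSE)
    switch(metric,
      auc = roc_auc(s, y),
      auprc = pr_auc(s, y),
      mcc = binary_metrics(confusion_counts(
              as.integer(s > thresholds[[m]]$threshold), y))$mcc,
      f1 = binary_metrics(confusion_counts(
              as.integer(s > thresholds[[m]]$threshold), y))$f1)
  }

  residue_metrics <- c("auc", "auprc", "mcc", "f1")
  residue_series <- NULL
  if (verdicts) {
    plan <- make_subsets(names(entries), "disjoint_5pct", seed, n_subsets)
    residue_series <- lapply(residue_metrics, function(metric)
      subset_metric_series(plan, function(ids)
        vapply(names(methods), function(m) pooled_metric(m, ids, metric), 0)))
    names(residue_series) <- residue_metrics
  }
  residue_tab <- do.call(rbind, lapply(names(methods), function(m) {
    r <- records[[m]]
    row <- data.frame(method = m, threshold = r$threshold,
                      coverage = 100 * r$coverage,
                      auc = r$auc, auprc = r$auprc, mcc = r$mcc, f1 = r$f1)
    if (verdicts) {
      for (metric in residue_metrics)
        row[[paste0(metric, "_verdict")]] <- fmt_verdict_cell(
          r[[metric]], verdict_symbols(residue_series[[metric]], m, compare_to))
    }
    row
  }))
  residue_tab <- residue_tab[order(-residue_tab$auc), ]

  idr_sets <- c("shortIDR", "longIDR", "bindingIDR", "non-terminusIDR")
  idr_tab <- do.call(rbind, lapply(names(methods), function(m) {
    row <- data.frame(method = m)
    for (ds in idr_sets) {
      ids <- membership_ids(membership, ds)
      val <- tryCatch(pooled_metric(m, ids, "auc"), error = function(e) NA_real_)
      cell <- val
      if (verdicts && length(ids) >= n_subsets) {
        plan_ds <- make_subsets(ids, "disjoint_5pct", seed, n_subsets)
        ser <- subset_metric_series(plan_ds, function(sub)
          vapply(names(methods), function(mm) pooled_metric(mm, sub, "auc"), 0))
        row[[paste0(ds, "_verdict")]] <- fmt_verdict_cell(
          val, verdict_symbols(ser, m, compare_to))
      }
      row[[ds]] <- val
    }
    row
  }))
  idr_tab <- idr_tab[match(residue_tab$method, idr_tab$method), ]

  content_series <- NULL
  if (verdicts) {
    plan <- make_subsets(names(entries), "disjoint_5pct", seed, n_subsets)
    content_eval <- function(metric) function(ids)
      vapply(names(methods), function(m) {
        sub <- intersect(ids, names(pred_content[[m]]))
        if (length(sub) < 2L) stop("no coverage")
        if (metric == "mae") content_mae(pred_content[[m]][sub], native_content[sub])
        else content_scc(pred_content[[m]][sub], native_content[sub])
      }, 0)
    content_series <- list(mae = subset_metric_series(plan, content_eval("mae")),
                           scc = subset_metric_series(plan, content_eval("scc")))
  }
  content_tab <- do.call(rbind, lapply(names(methods), function(m) {
    ids <- names(pred_content[[m]])
    row <- data.frame(method = m,
                      mae = content_mae(pred_content[[m]], native_content[ids]),
                      scc = content_scc(pred_content[[m]], native_content[ids]))
    if (verdicts) {
      row$mae_verdict <- fmt_verdict_cell(row$mae,
        verdict_symbols(content_series$mae, m, compare_to, higher_better = FALSE))
      row$scc_verdict <- fmt_verdict_cell(row$scc,
        verdict_symbols(content_series$scc, m, compare_to))
    }
    row
  }))
  content_tab <- content_tab[match(residue_tab$method, content_tab$method), ]

  fdp_plan <- if (verdicts)
    make_subsets(names(entries), "sampled_20pct", seed, n_subsets) else NULL
  fdp_tab <- do.call(rbind, lapply(names(methods), function(m) {
    row <- data.frame(method = m)
    for (cutoff in fdp_cutoffs) {
      tag <- sprintf("fdp%02d", round(100 * cutoff))
      ids <- names(pred_content[[m]])
      res <- tryCatch(fdp_eval(pred_content[[m]], native_content[ids], cutoff),
                      error = function(e) list(f1 = NA_real_, sensitivity = NA_real_))
      row[[paste0(tag, "_f1")]] <- res$f1
      row[[paste0(tag, "_sensitivity")]] <- res$sensitivity
      if (verdicts && !is.na(res$f1)) {
        for (metric in c("f1", "sensitivity")) {
          ser <- subset_metric_series(fdp_plan, function(ids2)
            vapply(names(methods), function(mm) {
              sub <- intersect(ids2, names(pred_content[[mm]]))
              fdp_eval(pred_content[[mm]][sub], native_content[sub], cutoff)[[metric]]
            }, 0))
          row[[paste0(tag, "_", metric, "_verdict")]] <- fmt_verdict_cell(
            res[[metric]], verdict_symbols(ser, m, compare_to))
        }
      }
    }
    row
  }))
  fdp_tab <- fdp_tab[match(residue_tab$method, fdp_tab$method), ]

  structure(list(summary = summary_tab, residue = residue_tab,
                 idr_auc = idr_tab, content = content_tab, fdp = fdp_tab,
                 thresholds = thresholds,
                 log = list(seed = as.integer(seed),
                            n_subsets = as.integer(n_subsets),
                            compare_to = compare_to,
                            n_proteins = length(entries),
                            methods = names(methods))),
            class = "benchmark_bundle")
}

#' Run the sequence-marker analysis
#'
#' Computes per-protein AUCs for the structure-derived predictor and the
#' panel of disorder predictors (fully disordered proteins, whose AUC is
#' undefined, are excluded), splits the cohort into competitive and rest,
#' compares the eight marker distributions, and applies the below-median
#' selection rule using the significant markers among `active`; the pooled
#' AUC of every method on the selected proteins is reported.
#'
#' @param entries Named list of [ref_entry] objects.
#' @param af2_profiles Named list of [score_profile] objects for the
#'   structure-derived predictor.
#' @param panel Named list (method -> named profile list) of disorder
#'   predictors.
#' @param disorder_binary,binding_binary,coil_binary Named lists of binary
#'   [score_profile] objects supplying the marker inputs.
#' @param auc_floor AUC floor for the competitive rule; defaults to the best
#'   panel method's dataset-level AUC.
#' @param active Candidate markers for the selection rule (only those found
#'   significant are applied).
#' @return List of class `marker_analysis` with the split, marker table,
#'   per-marker p-values, selected ids and the selected-set AUC per method.
#' @export
run_marker_analysis <- function(entries, af2_profiles, panel,
                                disorder_binary, binding_binary, coil_binary,
                                auc_floor = NULL,
                                active = c("seq_length", "binding_content",
                                           "n_putative_idrs", "composite")) {
  if (is.null(auc_floor)) {
    auc_floor <- max(vapply(panel, function(pr) {
      ids <- intersect(names(pr), names(entries))
      s <- unlist(lapply(ids, function(i) pr[[i]]$scores), use.names = FALSE)
      y <- unlist(lapply(ids, function(i) entries[[i]]$disorder), use.names = FALSE)
      roc_auc(s, y)
    }, 0))
  }
  af2_auc <- per_protein_auc(af2_profiles, entries)
  panel_auc <- do.call(cbind, lapply(panel, function(pr) {
    v <- per_protein_auc(pr, entries)
    v[names(af2_auc)]
  }))
  rownames(panel_auc) <- names(af2_auc)
  split <- competitive_split(af2_auc, panel_auc, auc_floor)
  markers <- marker_table(entries, disorder_binary, binding_binary, coil_binary)
  pvals <- compare_marker_distributions(split, markers)
  sig_active <- intersect(active, pvals$marker[pvals$significant])
  comp_markers <- markers[markers$id %in% split$competitive, , drop = FALSE]
  medians <- vapply(sig_active, function(m) stats::median(comp_markers[[m]]), 0)
  selected <- if (length(sig_active))
    marker_select(markers, medians, sig_active) else character()
  sel_auc <- if (length(selected)) {
    all_methods <- c(list(af2 = af2_profiles), panel)
    vapply(all_methods, function(pr) {
      ids <- intersect(selected, names(pr))
      s <- unlist(lapply(ids, function(i) pr[[i]]$scores), use.names = FALSE)
      y <- unlist(lapply(ids, function(i) entries[[i]]$disorder), use.names = FALSE)
      tryCatch(roc_auc(s, y), error = function(e) NA_real_)
    }, 0)
  } else numeric()
  structure(list(split = split, markers = markers, p_values = pvals,
                 active = sig_active, medians = medians,
                 selected = selected, selected_auc = sel_auc),
            class = "marker_analysis")
}

#' Write the report bundle as TSV and JSON twins
#'
#' Every table in the bundle is written both as a TSV and as a JSON file
#' with identical content, plus a `log.json` recording seeds, thresholds and
#' exclusions. Re-reading a JSON twin reconstructs the table.
#'
#' @param bundle A `benchmark_bundle` from [run_benchmark()].
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of written paths.
#' @export
emit_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("summary", "residue", "idr_auc", "content", "fdp")
  paths <- character()
  for (tab in tables) {
    df <- bundle[[tab]]
    tsv <- file.path(dir, paste0(tab, ".tsv"))
    json <- file.path(dir, paste0(tab, ".json"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(df, json, dataframe = "rows", digits = NA, na = "null")
    paths <- c(paths, tsv, json)
  }
  log <- bundle$log
  log$thresholds <- lapply(bundle$thresholds, unclass)
  log_path <- file.path(dir, "log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, log_path))
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("<benchmark_bundle> %d proteins, %d methods, seed %d\n",
              x$log$n_proteins, length(x$log$methods), x$log$seed))
  cat("residue-level table:\n")
  print(x$residue[, c("method", "threshold", "coverage", "auc", "auprc", "mcc", "f1")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
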