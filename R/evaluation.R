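# Scoring predictions against the known distribution: confusion metrics,
# rank-based AUC, holdout validation, the all-metrics > cutoff selection
# rule, and multi-leaf overlap as prediction uncertainty.

#' Confusion-matrix metrics for a binary prediction
#'
#' Sensitivity, specificity and the True Skill Statistic
#' (TSS = sensitivity + specificity - 1); the identity holds exactly.
#'
#' @param pred_binary,truth_binary Logical vectors over the same cells.
#' @return Object of class `eval_metrics`: `sensitivity`, `specificity`,
#'   `tss` and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred_binary, truth_binary) {
  stopifnot(length(pred_binary) == length(truth_binary))
  pred_binary <- as.logical(pred_binary)
  truth_binary <- as.logical(truth_binary)
  if (all(truth_binary) || !any(truth_binary))
    stop("truth is all-present or all-absent: sensitivity/specificity undefined")
  tp <- sum(pred_binary & truth_binary)
  fp <- sum(pred_binary & !truth_binary)
  tn <- sum(!pred_binary & !truth_binary)
  fn <- sum(!pred_binary & truth_binary)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1, tp = tp, fp = fp, tn = tn, fn = fn),
            class = "eval_metrics")
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with mid-rank handling of ties; identical to
#' counting concordant score pairs (ties count one half).
#'
#' @param scores Continuous suitability scores.
#' @param truth_binary Logical presence truth (both classes required).
#' @return AUC in \[0,1\].
#' @export
auc_score <- function(scores, truth_binary) {
  truth_binary <- as.logical(truth_binary)
  np <- sum(truth_binary); nn <- sum(!truth_binary)
  if (np == 0 || nn == 0)
    stop("AUC undefined: one class is absent from the truth")
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[truth_binary]) - np * (np + 1) / 2) / (np * nn)
}

#' Validate replicate-averaged predictions on the holdout cells
#'
#' For every (method, leaf) the replicate-averaged suitability is
#' prevalence-thresholded and scored on the holdout cells only (the cells
#' never touched by the modeling sample). Overlap between holdout and
#' modeling sample is an error, not a warning.
#'
#' @param surfaces Named list `surfaces[[method]][[leaf]]` of suitability
#'   vectors over *all* cells (cell order = `cell_ids`).
#' @param thresholds Named list `thresholds[[method]][[leaf]]` of prevalence
#'   thresholds.
#' @param cell_ids Cell ids for the surface rows.
#' @param holdout_ids,sample_ids Holdout and modeling-sample cell ids.
#' @param truth_leaf Leaf id truth per cell (same order as `cell_ids`).
#' @return Data frame: `method`, `leaf`, `sensitivity`, `specificity`,
#'   `tss`, `auc`, `n`.
#' @export
external_validate <- function(surfaces, thresholds, cell_ids, holdout_ids,
                              sample_ids, truth_leaf) {
  if (length(intersect(holdout_ids, sample_ids)))
    stop("holdout cells overlap the modeling sample")
  ix <- match(holdout_ids, cell_ids)
  if (anyNA(ix)) stop("holdout ids not found among cells")
  rows <- list()
  for (m in names(surfaces)) {
    for (leaf in names(surfaces[[m]])) {
      s <- surfaces[[m]][[leaf]][ix]
      truth <- truth_leaf[ix] == as_leaf_id(leaf)
      cm <- confusion_metrics(binarize_quiet(s, thresholds[[m]][[leaf]]),
                              truth)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, leaf = leaf, sensitivity = cm$sensitivity,
        specificity = cm$specificity, tss = cm$tss,
        auc = auc_score(s, truth), n = length(s))
    }
  }
  do.call(rbind, rows)
}

as_leaf_id <- function(x) suppressWarnings({
  n <- as.integer(x); if (is.na(n)) x else n
})

binarize_quiet <- function(s, thr) suppressMessages(binarize(s, thr))

#' Select adequate methods (all metrics above the cutoff)
#'
#' A method is adequate when *every* metric (sensitivity, specificity, TSS,
#' AUC) exceeds the cutoff — strictly — for every leaf; `per_leaf = FALSE`
#' instead applies the rule to the across-leaf mean of each metric.
#'
#' @param metrics_table Output of [external_validate()] (columns `method`,
#'   `leaf`, `sensitivity`, `specificity`, `tss`, `auc`).
#' @param cutoff Threshold (default 0.7).
#' @param per_leaf Apply the rule to the per-leaf minimum (default) or to
#'   leaf-averaged metrics.
#' @return Character vector of adequate method ids; the ranked per-method
#'   worst metric is attached as attribute `"report"`.
#' @export
select_methods <- function(metrics_table, cutoff = 0.7, per_leaf = TRUE) {
  if (is.null(metrics_table) || nrow(metrics_table) == 0)
    stop("empty metrics table")
  metric_cols <- c("sensitivity", "specificity", "tss", "auc")
  agg <- if (per_leaf) {
    stats::aggregate(metrics_table[metric_cols],
                     by = list(method = metrics_table$method), FUN = min)
  } else {
    stats::aggregate(metrics_table[metric_cols],
                     by = list(method = metrics_table$method), FUN = mean)
  }
  agg$worst <- do.call(pmin, agg[metric_cols])
  agg <- agg[order(-agg$worst), ]
  selected <- agg$method[agg$worst > cutoff]
  structure(as.character(selected), report = agg)
}

#' Per-cell multi-leaf overlap (prediction uncertainty)
#'
#' Only one landcover category can occupy a cell, so any cell where more
#' than one leaf is predicted present is an uncertain prediction. Reports
#' the per-cell overlap count and, per leaf, the area of its range flagged
#' uncertain. Uncertain cells are reported, never removed.
#'
#' @param leaf_binaries Logical cells x leaves matrix (one scenario, one GCM).
#' @param cell_areas Cell areas in km^2 (same cell order).
#' @return List: `count` (per-cell overlap count), `uncertain` (logical,
#'   count >= 2), `uncertain_area_km2` (total), `per_leaf_area_km2`.
#' @export
uncertainty_map <- function(leaf_binaries, cell_areas) {
  leaf_binaries <- as.matrix(leaf_binaries)
  if (nrow(leaf_binaries) != length(cell_areas))
    stop("leaf surfaces and cell areas are on different grids")
  count <- rowSums(leaf_binaries)
  uncertain <- count >= 2
  per_leaf <- apply(leaf_binaries, 2, function(b)
    sum(cell_areas[b & uncertain]))
  list(count = count, uncertain = uncertain,
       uncertain_area_km2 = sum(cell_areas[uncertain]),
       per_leaf_area_km2 = per_leaf)
}
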