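# Climatic partition: group grid cells into climatically homogeneous leaves
# with a CART classification tree (Gini impurity, cost-complexity pruning
# selected by repeated cross-validation with the 1-SE rule), validate the
# grouping with a random forest, and test robustness to anthropogenic cover.

#' Fit a classification tree of landcover on climate
#'
#' Greedy binary recursive partitioning (Gini impurity, one variable per
#' split) of the cells' landcover category on their climate vector, grown
#' deep (complexity penalty `cp_min`) so that [prune_by_cv()] can select the
#' right size afterwards. A single-category input or all-constant predictors
#' yield a root-only tree (the latter with a warning).
#'
#' @param cells Cell table with a `landcover` column and climate columns.
#' @param climate_vars Predictor columns (default bio1..bio19).
#' @param min_node_size Minimum number of cells a node must hold to be
#'   considered for splitting (rpart `minsplit`); default 20.
#' @param cp_min Complexity penalty used while growing (default 1e-4).
#' @return Object of class `lc_tree` wrapping the rpart fit together with
#'   the training data (needed by the pruning cross-validation).
#' @export
fit_tree <- function(cells, climate_vars = paste0("bio", 1:19),
                     min_node_size = 20, cp_min = 1e-4) {
  missing_vars <- setdiff(climate_vars, names(cells))
  if (length(missing_vars))
    stop("cells lack climate column(s): ", paste(missing_vars, collapse = ", "))
  dat <- cells[, climate_vars, drop = FALSE]
  dat$.lc <- factor(cells$landcover)
  if (anyNA(dat)) stop("cells with missing climate or landcover")
  if (nrow(dat) < min_node_size)
    stop("fewer cells than min_node_size")

  constant <- vapply(dat[climate_vars], function(x) length(unique(x)) <= 1,
                     logical(1))
  root_only <- FALSE
  if (nlevels(dat$.lc) < 2) {
    root_only <- TRUE
  } else if (all(constant)) {
    warning("all climate predictors are constant; returning a root-only tree")
    root_only <- TRUE
  }

  fit <- if (root_only) NULL else
    rpart::rpart(.lc ~ ., data = dat, method = "class",
                 parms = list(split = "gini"),
                 control = rpart::rpart.control(
                   minsplit = min_node_size, cp = cp_min, xval = 0,
                   maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  structure(list(fit = fit, data = dat, climate_vars = climate_vars,
                 min_node_size = min_node_size, cp_min = cp_min,
                 levels = levels(dat$.lc), pruned = FALSE),
            class = "lc_tree")
}

#' @export
print.lc_tree <- function(x, ...) {
  cat(sprintf("lc_tree: %d leaves over %d cells (%spruned)\n",
              n_leaves(x), nrow(x$data), if (x$pruned) "" else "un"))
  invisible(x)
}

#' Number of leaves of a fitted tree
#' @param tree An `lc_tree`.
#' @export
n_leaves <- function(tree) {
  if (is.null(tree$fit)) return(1L)
  sum(tree$fit$frame$var == "<leaf>")
}

# Variables actually used by the (pruned) tree's splits.
#' Climate variables used by the tree's splits
#' @param tree An `lc_tree`.
#' @return Character vector (empty for a root-only tree).
#' @export
tree_variables <- function(tree) {
  if (is.null(tree$fit)) return(character(0))
  v <- as.character(tree$fit$frame$var)
  unique(v[v != "<leaf>"])
}

# Split thresholds, named by split variable, in preorder.
tree_splits <- function(tree) {
  if (is.null(tree$fit) || is.null(tree$fit$splits)) return(numeric(0))
  frame <- tree$fit$frame
  internal <- frame$var != "<leaf>"
  stats::setNames(tree$fit$splits[, "index"][seq_len(sum(internal))],
                  as.character(frame$var[internal]))
}

#' Select tree size by repeated cross-validation (cost-complexity pruning)
#'
#' Re-runs rpart's k-fold cross-validation `n_reps` times on the stored
#' training data, averages the relative cross-validated error along the
#' cost-complexity path, and prunes at the smallest subtree whose mean CV
#' error is within one standard error of the minimum (1-SE rule).
#'
#' @param tree An `lc_tree` from [fit_tree()].
#' @param n_reps Number of CV repetitions (default 200; raise for
#'   high-fidelity runs).
#' @param k_folds Folds per repetition (default 10).
#' @param seed Seed controlling fold assignment.
#' @param use_1se Apply the 1-SE rule (default); `FALSE` picks the plain
#'   CV-error minimiser.
#' @return A pruned `lc_tree` (a subtree of the input); carries the averaged
#'   complexity path as attribute `cv_path` and the selected penalty as
#'   `cp_selected`.
#' @export
prune_by_cv <- function(tree, n_reps = 200, k_folds = 10, seed = 1,
                        use_1se = TRUE) {
  stopifnot(inherits(tree, "lc_tree"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(tree$fit) || n_leaves(tree) == 1) {
    tree$pruned <- TRUE
    return(tree)
  }
  base_cp <- tree$fit$cptable
  xerr_sum <- rep(0, nrow(base_cp))
  xstd_sum <- rep(0, nrow(base_cp))
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    fit_r <- rpart::rpart(.lc ~ ., data = tree$data, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = tree$min_node_size, cp = tree$cp_min,
                            xval = k_folds, maxcompete = 0, maxsurrogate = 0,
                            usesurrogate = 0))
    cpt <- fit_r$cptable
    if (nrow(cpt) != nrow(base_cp))
      stop("cost-complexity path changed between refits (unexpected)")
    xerr_sum <- xerr_sum + cpt[, "xerror"]
    xstd_sum <- xstd_sum + cpt[, "xstd"]
  }
  xerr <- xerr_sum / n_reps
  xstd <- xstd_sum / n_reps
  i_min <- which.min(xerr)
  i_sel <- if (use_1se) {
    cand <- which(xerr <= xerr[i_min] + xstd[i_min])
    min(cand)  # earliest row = largest cp = smallest tree within 1 SE
  } else i_min
  # prune at the geometric mean between the selected cp and the next larger
  cp_sel <- if (i_sel == 1) Inf else
    sqrt(base_cp[i_sel, "CP"] * base_cp[i_sel - 1, "CP"])
  pruned_fit <- if (is.infinite(cp_sel)) {
    rpart::prune(tree$fit, cp = base_cp[1, "CP"] * 1.01)
  } else rpart::prune(tree$fit, cp = cp_sel)
  out <- tree
  out$fit <- pruned_fit
  out$pruned <- TRUE
  attr(out, "cv_path") <- data.frame(cp = base_cp[, "CP"],
                                     nsplit = base_cp[, "nsplit"],
                                     xerror = xerr, xstd = xstd)
  attr(out, "cp_selected") <- base_cp[i_sel, "CP"]
  out
}

# Descend the rpart tree for each row of newdata; returns node numbers.
# With maxcompete = maxsurrogate = 0 the primary split of the i-th internal
# frame row is the i-th row of fit$splits. Continuous split convention:
# ncat == -1 sends x < threshold left, ncat == +1 sends x >= threshold left.
rpart_leaf_nodes <- function(fit, newdata) {
  frame <- fit$frame
  node_of_row <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  split_var <- as.character(frame$var[internal])
  split_thr <- fit$splits[seq_along(internal), "index"]
  split_dir <- fit$splits[seq_along(internal), "ncat"]
  split_ix <- stats::setNames(seq_along(internal), node_of_row[internal])
  row_of_node <- stats::setNames(seq_len(nrow(frame)), node_of_row)

  out <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    node <- 1L
    repeat {
      r <- row_of_node[[as.character(node)]]
      if (frame$var[r] == "<leaf>") break
      s <- split_ix[[as.character(node)]]
      x <- newdata[i, split_var[s]]
      go_left <- if (split_dir[s] < 0) x < split_thr[s] else x >= split_thr[s]
      node <- if (go_left) 2L * node else 2L * node + 1L
    }
    out[i] <- node
  }
  out
}

#' Assign cells to tree leaves
#'
#' Each cell descends the (pruned) tree to its leaf; the leaf's predicted
#' category is the modal training category of that leaf. The result also
#' reports, per original category, the share of its cells sitting in leaves
#' that predict a *different* category (the reclassification diagnostic),
#' both overall and per category.
#'
#' @param tree An `lc_tree`.
#' @param cells Cell table with the tree's climate columns (and, if present,
#'   a `landcover` column used for the reclassification shares).
#' @return Object of class `leaf_partition`: `assignment` data frame
#'   (`cell_id`, `leaf_id`, `predicted_category`), `leaves` summary
#'   (`leaf_id`, `predicted_category`, `n`), `reclassified` (overall share
#'   and per-category table, `NA` when `landcover` is absent), and
#'   `gcm_id` provenance (attribute set by the caller).
#' @export
assign_leaves <- function(tree, cells) {
  stopifnot(inherits(tree, "lc_tree"))
  vars <- tree$climate_vars
  if (anyNA(cells[, intersect(vars, names(cells))]))
    stop("cells with missing climate values")
  if (is.null(tree$fit)) {
    leaf <- rep(1L, nrow(cells))
    pred <- rep(levels(tree$data$.lc)[which.max(table(tree$data$.lc))],
                nrow(cells))
  } else {
    missing_vars <- setdiff(tree_variables(tree), names(cells))
    if (length(missing_vars))
      stop("cells lack climate column(s): ",
           paste(missing_vars, collapse = ", "))
    leaf <- rpart_leaf_nodes(tree$fit, as.data.frame(cells))
    ylev <- attr(tree$fit, "ylevels")
    frame <- tree$fit$frame
    row_of_node <- stats::setNames(seq_len(nrow(frame)),
                                   as.integer(rownames(frame)))
    pred <- ylev[frame$yval[row_of_node[as.character(leaf)]]]
  }
  assignment <- data.frame(cell_id = if ("cell_id" %in% names(cells))
    cells$cell_id else seq_len(nrow(cells)),
    leaf_id = leaf, predicted_category = pred)
  leaves <- unique(assignment[, c("leaf_id", "predicted_category")])
  leaves <- leaves[order(leaves$leaf_id), ]
  leaves$n <- as.integer(table(assignment$leaf_id)[as.character(leaves$leaf_id)])
  rownames(leaves) <- NULL
  reclassified <- list(overall = NA_real_, by_category = NULL)
  if ("landcover" %in% names(cells)) {
    diff <- cells$landcover != pred
    reclassified$overall <- mean(diff)
    reclassified$by_category <- tapply(diff, cells$landcover, mean)
  }
  structure(list(assignment = assignment, leaves = leaves,
                 reclassified = reclassified),
            class = "leaf_partition")
}

#' @export
print.leaf_partition <- function(x, ...) {
  cat(sprintf("leaf_partition: %d leaves over %d cells", nrow(x$leaves),
              nrow(x$assignment)))
  if (!is.na(x$reclassified$overall))
    cat(sprintf("; %.1f%% of cells reclassified", 100 * x$reclassified$overall))
  cat("\n")
  invisible(x)
}

#' Random-forest check of the climatic grouping
#'
#' Bagged trees (bootstrap rows, random variable subset per split) of
#' landcover on climate; the out-of-bag classification accuracy is reported
#' as the proportion of variation the climatic grouping explains, together
#' with each cell's out-of-bag vote share for its true category.
#'
#' @param cells Cell table with `landcover` and climate columns.
#' @param n_trees Number of trees (default 500).
#' @param seed Seed.
#' @param climate_vars Predictors.
#' @return List with `explained_proportion` (OOB accuracy), `cell_prob`
#'   (per-cell OOB vote share for the true category), `oob_predicted`
#'   (per-cell OOB class) and the fitted forest.
#' @export
random_forest_check <- function(cells, n_trees = 500, seed = 1,
                                climate_vars = paste0("bio", 1:19)) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  x <- as.matrix(cells[, climate_vars, drop = FALSE])
  y <- factor(cells$landcover)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  oob_pred <- rf$predicted
  votes <- rf$votes  # OOB vote fractions
  cell_prob <- votes[cbind(seq_along(y), match(as.character(y),
                                               colnames(votes)))]
  list(explained_proportion = mean(oob_pred == y, na.rm = TRUE),
       cell_prob = cell_prob,
       oob_predicted = oob_pred,
       forest = rf)
}

#' Sensitivity of the classification to anthropogenic cover
#'
#' Re-runs the random-forest classification after removing cells with more
#' than `fraction_cutoff` anthropogenic cover and compares the proportion of
#' correctly classified cells; additionally fits a logistic regression of
#' per-cell correctness on the anthropogenic fraction and reports the slope
#' with a nonparametric bootstrap interval.
#'
#' @param cells Cell table with `landcover`, climate columns and
#'   `anthro_fraction`.
#' @param fraction_cutoff Removal threshold (default 0.5).
#' @param n_trees Trees per forest.
#' @param seed Seed.
#' @param n_boot Bootstrap replicates for the slope interval (default 200).
#' @param climate_vars Predictors.
#' @return List with `accuracy_all`, `accuracy_filtered`, `n_filtered`,
#'   and `trend` (`slope`, `ci_lower`, `ci_upper`; `NA` when the fraction
#'   is constant).
#' @export
anthropogenic_sensitivity <- function(cells, fraction_cutoff = 0.5,
                                      n_trees = 500, seed = 1, n_boot = 200,
                                      climate_vars = paste0("bio", 1:19)) {
  if (!"anthro_fraction" %in% names(cells))
    stop("cells lack an anthro_fraction column")
  keep <- cells$anthro_fraction <= fraction_cutoff
  if (!any(keep)) stop("no cells remain after the anthropogenic filter")

  all_check <- random_forest_check(cells, n_trees, seed, climate_vars)
  filt_check <- if (all(keep)) all_check else
    random_forest_check(cells[keep, , drop = FALSE], n_trees, seed,
                        climate_vars)

  correct <- as.integer(all_check$oob_predicted ==
                          factor(cells$landcover))
  frac <- cells$anthro_fraction
  trend <- list(slope = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
  if (length(unique(frac)) > 1 && length(unique(correct)) > 1) {
    fit <- suppressWarnings(stats::glm(correct ~ frac, family = stats::binomial()))
    trend$slope <- unname(stats::coef(fit)["frac"])
    set.seed(as.integer(seed))
    boots <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      ix <- sample.int(length(correct), replace = TRUE)
      if (length(unique(correct[ix])) < 2 || length(unique(frac[ix])) < 2) next
      bf <- suppressWarnings(stats::glm(correct[ix] ~ frac[ix],
                                        family = stats::binomial()))
      boots[b] <- unname(stats::coef(bf)[2])
    }
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    trend$ci_lower <- unname(qs[1]); trend$ci_upper <- unname(qs[2])
  }
  list(accuracy_all = all_check$explained_proportion,
       accuracy_filtered = filt_check$explained_proportion,
       n_filtered = sum(keep), trend = trend)
}
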