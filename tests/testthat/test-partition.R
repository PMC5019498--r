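test_that("a clean two-class split is recovered with the threshold inside the gap", {
  cells <- separable_cells(gap = c(20, 24))
  tree <- fit_tree(cells, min_node_size = 10)
  expect_equal(n_leaves(tree), 2)
  splits <- landrefugia:::tree_splits(tree)
  expect_named(splits, "bio1")
  expect_gt(splits[[1]], 20)
  expect_lt(splits[[1]], 24)
  part <- assign_leaves(tree, cells)
  expect_equal(part$reclassified$overall, 0)
  # root impurity of a balanced two-class mix: Gini = 1 - 0.5^2 - 0.5^2
  p <- prop.table(table(cells$landcover))
  expect_equal(1 - sum(p^2), 0.5)
})

test_that("an XOR layout needs depth two; brute force shows no single split suffices", {
  n <- c(30, 30, 30, 60)  # imbalance so the first gap split has positive gain
  quad <- rep(1:4, n)
  # two exact levels per axis: the only candidate splits are the midpoints
  x1 <- ifelse(quad %in% c(1, 3), 0, 3)
  x2 <- ifelse(quad %in% c(1, 2), 0, 3)
  lab <- ifelse(quad %in% c(1, 4), "a", "b")
  cells <- data.frame(bio1 = x1, bio2 = x2, landcover = lab)

  # oracle: enumerate every single-variable split
  best_single <- 0
  for (v in c("bio1", "bio2")) for (t in sort(unique(cells[[v]]))) {
    for (side in list(cells[[v]] <= t, cells[[v]] > t)) {
      pred <- ifelse(side, "a", "b")
      best_single <- max(best_single, mean(pred == lab))
    }
  }
  expect_lt(best_single, 1)

  tree <- fit_tree(cells, climate_vars = c("bio1", "bio2"), min_node_size = 10)
  expect_gte(n_leaves(tree), 3)  # >= 3 nodes of splitting structure
  expect_equal(assign_leaves(tree, cells)$reclassified$overall, 0)
})

test_that("CV pruning keeps a noiseless tree and collapses pure-noise labels to the root", {
  w <- noiseless_world(cell_size = 1)
  full <- fit_tree(w$cells_clim)
  pruned <- prune_by_cv(full, n_reps = 20, seed = 3)
  expect_equal(n_leaves(pruned), n_leaves(full))
  expect_lte(n_leaves(pruned), n_leaves(full))

  set.seed(8)
  noise <- w$cells_clim
  noise$landcover <- sample(c("shrubland", "closed_forest"), nrow(noise),
                            replace = TRUE)
  noisy_full <- fit_tree(noise)
  noisy_pruned <- prune_by_cv(noisy_full, n_reps = 20, seed = 3)
  expect_equal(n_leaves(noisy_pruned), 1)
  expect_error(prune_by_cv(full, n_reps = 0), "n_reps")
})

test_that("leaf assignment matches rpart's internal placement and reports reclassification", {
  w <- noiseless_world(cell_size = 1)
  set.seed(2)
  mixed <- w$cells_clim
  mixed$bio1 <- mixed$bio1 + stats::rnorm(nrow(mixed), 0, 0.4)
  tree <- fit_tree(mixed)
  nodes_rpart <- as.integer(rownames(tree$fit$frame))[tree$fit$where]
  nodes_mine <- landrefugia:::rpart_leaf_nodes(tree$fit, mixed)
  expect_identical(nodes_mine, nodes_rpart)

  # single-category input: root-only tree predicting the modal category
  single <- mixed
  single$landcover <- "shrubland"
  rt <- fit_tree(single)
  expect_equal(n_leaves(rt), 1)
  pr <- assign_leaves(rt, single)
  expect_true(all(pr$assignment$predicted_category == "shrubland"))
  expect_equal(pr$reclassified$overall, 0)

  # two categories sharing one climatic envelope collapse to one prediction;
  # the reclassified share equals the minority share
  set.seed(5)
  shared <- data.frame(landcover = rep(c("shrubland", "open_vegetation"),
                                       times = c(60, 40)))
  clim <- matrix(stats::rnorm(100 * 19), 100)
  colnames(clim) <- paste0("bio", 1:19)
  shared <- cbind(shared, as.data.frame(clim))
  stree <- prune_by_cv(fit_tree(shared), n_reps = 10, seed = 1)
  spart <- assign_leaves(stree, shared)
  expect_equal(length(unique(spart$assignment$predicted_category)), 1)
  expect_equal(spart$reclassified$overall, 0.4)
  expect_equal(unname(spart$reclassified$by_category[["open_vegetation"]]), 1)

  # constant predictors: root-only with a warning
  const <- shared
  const[paste0("bio", 1:19)] <- 1
  expect_warning(ct <- fit_tree(const), "constant")
  expect_equal(n_leaves(ct), 1)
})

test_that("weighted Gini impurity never increases from parent to children", {
  w <- noiseless_world(cell_size = 1)
  set.seed(3)
  mixed <- w$cells_clim
  mixed$bio1 <- mixed$bio1 + stats::rnorm(nrow(mixed), 0, 0.3)
  tree <- fit_tree(mixed)
  frame <- tree$fit$frame
  nodes <- as.integer(rownames(frame))
  counts <- frame$yval2[, 1 + seq_len(nlevels(tree$data$.lc)), drop = FALSE]
  gini <- function(cnt) 1 - sum((cnt / sum(cnt))^2)
  for (i in which(frame$var != "<leaf>")) {
    kids <- match(c(2 * nodes[i], 2 * nodes[i] + 1), nodes)
    parent_g <- gini(counts[i, ])
    child_g <- (sum(counts[kids[1], ]) * gini(counts[kids[1], ]) +
                  sum(counts[kids[2], ]) * gini(counts[kids[2], ])) /
      sum(counts[i, ])
    expect_lte(child_g, parent_g + 1e-12)
  }
})

test_that("the random forest check explains separable data and stays at chance on noise", {
  cells <- separable_cells(n_per = 80)
  rf <- random_forest_check(cells, n_trees = 100, seed = 1)
  expect_gt(rf$explained_proportion, 0.95)
  expect_true(all(rf$cell_prob >= 0 & rf$cell_prob <= 1))

  set.seed(6)
  noise <- cells
  noise$landcover <- sample(noise$landcover)
  noise[paste0("bio", 1:19)] <- matrix(stats::rnorm(nrow(noise) * 19),
                                       nrow(noise))
  rf2 <- random_forest_check(noise, n_trees = 200, seed = 1)
  expect_lt(abs(rf2$explained_proportion - 0.5), 0.12)
  expect_error(random_forest_check(cells, n_trees = 0), "n_trees")
})

test_that("anthropogenic sensitivity compares filtered accuracy and detects no spurious trend", {
  cells <- separable_cells(n_per = 60)
  cells$anthro_fraction <- 0
  s0 <- anthropogenic_sensitivity(cells, n_trees = 100, seed = 2, n_boot = 20)
  expect_equal(s0$accuracy_all, s0$accuracy_filtered)

  # fractions of 1 exactly on mislabeled cells: the filtered forest is clean
  set.seed(7)
  flip <- sample(nrow(cells), 12)
  cells2 <- cells
  cells2$landcover[flip] <- ifelse(cells2$landcover[flip] == "shrubland",
                                   "closed_forest", "shrubland")
  cells2$anthro_fraction <- 0
  cells2$anthro_fraction[flip] <- 1
  s2 <- anthropogenic_sensitivity(cells2, n_trees = 100, seed = 2, n_boot = 20)
  expect_equal(s2$accuracy_filtered, 1)
  expect_lt(s2$accuracy_all, 1)

  # fractions independent of correctness: the bootstrap interval covers 0
  set.seed(9)
  cells3 <- cells2
  cells3$anthro_fraction <- stats::runif(nrow(cells3))
  s3 <- anthropogenic_sensitivity(cells3, n_trees = 100, seed = 2, n_boot = 100)
  expect_lt(s3$trend$ci_lower, 0)
  expect_gt(s3$trend$ci_upper, 0)

  cells4 <- cells
  cells4$anthro_fraction <- 0.9
  expect_error(anthropogenic_sensitivity(cells4, fraction_cutoff = 0.5),
               "no cells remain")
})
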