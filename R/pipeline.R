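# End-to-end orchestration: simulate -> partition -> model -> project ->
# refugia, reproducible from (config, seed), with a job registry, a
# structured log and plain-text artifacts.

#' Method families
#'
#' The three ensemble families: envelope/distance models, statistical
#' models, and machine-learning models.
#' @return Named list of method id vectors.
#' @export
method_families <- function() {
  list(envelope_distance = c("bioclim", "gower", "mahalanobis"),
       statistical = c("glm", "gam", "mars"),
       machine_learning = c("maxent_like", "garp_like", "rf"))
}

#' Default run configuration
#'
#' The synthetic study conditions: a 40 x 40 grid of 0.5 degree cells
#' (20S-0, 70W-50W), 19 climate variables with small observation noise,
#' five landcover categories from nested threshold rules, three pseudo-GCMs
#' with nested RCP4.5/RCP8.5 shifts, a 25% modeling sample with 10
#' replicates of 75/25 calibration/validation, the statistical model family,
#' the all-metrics > 0.7 selection rule, and unanimity cross-GCM consensus.
#'
#' @return Nested configuration list accepted by [run_all()].
#' @export
default_config <- function() {
  list(
    synthetic = list(
      domain = list(lat_min = -20, lat_max = 0, lon_min = -70,
                    lon_max = -50, cell_size = 0.5),
      noise_sd = c(0.15, 20),
      smooth_noise = FALSE,
      gcms = default_gcms(),
      rcps = c("RCP4.5", "RCP8.5"),
      hotspots = list(list(lat = -5, lon = -65, radius = 3, intensity = 0.7),
                      list(lat = -15, lon = -55, radius = 2.5, intensity = 0.9))
    ),
    partition = list(min_node_size = 20, cv_reps = 50, k_folds = 10),
    modeling = list(methods = c("glm", "gam", "mars"), sample_frac = 0.25,
                    calib_frac = 0.75, n_reps = 10, cutoff = 0.7),
    projection = list(family = "statistical", consensus = "unanimity"),
    refugia = list(regions_file = NULL, nx = 2, ny = 2),
    sensitivity = list(enabled = TRUE, n_trees = 200, n_boot = 100),
    seed = 42
  )
}

#' Validate a run configuration
#'
#' Schema-level checks performed before any computation: unknown method ids,
#' families or consensus rules fail immediately.
#'
#' @param config Configuration list (see [default_config()]).
#' @return The config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  need <- c("synthetic", "partition", "modeling", "projection", "refugia",
            "seed")
  missing_blocks <- setdiff(need, names(config))
  if (length(missing_blocks))
    stop("config lacks block(s): ", paste(missing_blocks, collapse = ", "))
  bad <- setdiff(config$modeling$methods, SDM_METHODS)
  if (length(bad))
    stop("unknown method id(s): ", paste(bad, collapse = ", "))
  if (!config$projection$family %in% names(method_families()))
    stop("unknown ensemble family: ", config$projection$family)
  if (!config$projection$consensus %in% c("unanimity", "majority"))
    stop("unknown consensus rule: ", config$projection$consensus)
  if (length(config$synthetic$gcms) < 2)
    stop("need at least 2 GCMs for the consensus step")
  invisible(config)
}

derive_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 2147483629L

#' Run the full pipeline
#'
#' Executes simulate, partition, model, evaluate, project and refugia stages
#' in order. Every stage is a pure function of the config and seed; rerunning
#' with the same config yields identical artifacts.
#'
#' @param config Configuration (see [default_config()]); validated before
#'   any compute.
#' @param out_dir Optional directory for artifacts (CSV tables, `.asc`
#'   refuge masks, a JSON summary, the resolved config and a JSONL log).
#' @param quiet Suppress progress messages.
#' @return Object of class `refuge_report` (see the methods vignette for the
#'   component list).
#' @export
run_all <- function(config = default_config(), out_dir = NULL, quiet = FALSE) {
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  say <- function(stage, ...) {
    msg <- sprintf(...)
    log[[length(log) + 1]] <<- list(stage = stage, message = msg,
                                    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  seed <- config$seed
  syn <- config$synthetic
  domain <- do.call(domain_spec, syn$domain)
  rules <- default_rules()
  registry <- default_categories()
  native_cats <- registry$label[registry$native]
  gcm_ids <- names(syn$gcms)
  rcps <- syn$rcps

  ## -- simulate ------------------------------------------------------------
  truth_base <- generate_climate(domain,
                                 scenario_spec(gcm_ids[1], "baseline"),
                                 noise_sd = 0, seed = 1)
  landcover <- generate_landcover(truth_base, rules)
  cells <- apply_anthropogenic(landcover, domain, syn$hotspots,
                               seed = derive_seed(seed, 7L))
  stacks <- list(); truth_fut <- list()
  for (i in seq_along(gcm_ids)) {
    g <- gcm_ids[i]; p <- syn$gcms[[g]]
    sseed <- derive_seed(seed, i)
    mk <- function(rcp) scenario_spec(g, rcp, d_temp = p$d_temp,
                                      d_prec = p$d_prec)
    stacks[[g]] <- list(baseline = generate_climate(domain, mk("baseline"),
                                                    syn$noise_sd, sseed,
                                                    syn$smooth_noise))
    for (rcp in rcps) {
      stacks[[g]][[rcp]] <- generate_climate(domain, mk(rcp), syn$noise_sd,
                                             sseed, syn$smooth_noise)
      truth_fut[[g]][[rcp]] <- true_future_distribution(
        rules, truth_base, generate_climate(domain, mk(rcp), 0, 1))
    }
  }
  truth_current <- vapply(native_cats, function(k) landcover == k,
                          logical(nrow(cells)))
  # truth refuge consensus: category survives under every GCM's future
  truth_refuge <- lapply(rcps, function(rcp) {
    mats <- lapply(gcm_ids, function(g)
      pad_categories(truth_fut[[g]][[rcp]]$refuge, native_cats))
    Reduce(`&`, mats)
  })
  names(truth_refuge) <- rcps
  say("simulate", "%d cells, %d GCMs, %d categories", nrow(cells),
      length(gcm_ids), length(native_cats))

  ## -- partition -----------------------------------------------------------
  partitions <- list(); trees <- list()
  for (g in gcm_ids) {
    cells_g <- cbind(cells, as.data.frame(stacks[[g]]$baseline$values))
    tree <- fit_tree(cells_g, min_node_size = config$partition$min_node_size)
    tree <- prune_by_cv(tree, n_reps = config$partition$cv_reps,
                        k_folds = config$partition$k_folds,
                        seed = derive_seed(seed, 20L + match(g, gcm_ids)))
    if (n_leaves(tree) < 2)
      stop("partition stage: the pruned tree for ", g,
           " is root-only; cannot model a single leaf")
    trees[[g]] <- tree
    partitions[[g]] <- assign_leaves(tree, cells_g)
    say("partition", "%s: %d leaves, vars: %s, %.1f%% reclassified", g,
        n_leaves(tree), paste(tree_variables(tree), collapse = ","),
        100 * partitions[[g]]$reclassified$overall)
  }

  ## -- sensitivity (optional diagnostic) ------------------------------------
  sens_report <- NULL
  if (isTRUE(config$sensitivity$enabled)) {
    cells_s <- cbind(cells, as.data.frame(stacks[[gcm_ids[1]]]$baseline$values))
    sens_report <- anthropogenic_sensitivity(
      cells_s, n_trees = config$sensitivity$n_trees,
      seed = derive_seed(seed, 31L), n_boot = config$sensitivity$n_boot)
    say("sensitivity", "accuracy all=%.3f filtered=%.3f slope=%.3f",
        sens_report$accuracy_all, sens_report$accuracy_filtered,
        sens_report$trend$slope)
  }

  ## -- model ---------------------------------------------------------------
  mdl <- config$modeling
  design <- make_design(cells$cell_id, mdl$sample_frac, mdl$calib_frac,
                        mdl$n_reps, seed = derive_seed(seed, 40L))
  scenarios <- c("baseline", rcps)
  fits_summary <- list()   # per gcm: surfaces/thresholds/internal tss
  n_jobs_run <- 0L
  for (g in gcm_ids) {
    part <- partitions[[g]]
    vars_g <- tree_variables(trees[[g]])
    leaf_of <- stats::setNames(part$assignment$leaf_id,
                               part$assignment$cell_id)
    stack_vals <- lapply(scenarios, function(sc)
      stacks[[g]][[sc]]$values[, vars_g, drop = FALSE])
    names(stack_vals) <- scenarios
    cells_clim <- as.data.frame(stacks[[g]]$baseline$values)
    cells_clim$cell_id <- cells$cell_id

    leaves_g <- part$leaves$leaf_id
    eligible <- vapply(leaves_g, function(leaf) {
      all(vapply(design$replicates, function(rep) {
        calib_leaves <- leaf_of[as.character(rep$calib)]
        valid_leaves <- leaf_of[as.character(rep$valid)]
        sum(calib_leaves == leaf) >= 5 &&
          sum(valid_leaves == leaf) >= 1 &&
          sum(valid_leaves != leaf) >= 1
      }, logical(1)))
    }, logical(1))
    if (any(!eligible))
      say("model", "%s: skipping %d leaf(s) with too few sampled presences",
          g, sum(!eligible))
    leaves_use <- leaves_g[eligible]

    surf <- list(); thr <- list(); itss <- list()
    for (m in mdl$methods) {
      surf[[m]] <- list(); thr[[m]] <- list(); itss[[m]] <- list()
      for (leaf in leaves_use) {
        lf <- as.character(leaf)
        acc <- lapply(scenarios, function(sc)
          numeric(nrow(cells)))
        names(acc) <- scenarios
        prev_acc <- 0; tss_acc <- c()
        for (r in seq_len(mdl$n_reps)) {
          rep <- design$replicates[[r]]
          calib_ix <- match(rep$calib, cells$cell_id)
          train <- make_train_set(cells_clim[calib_ix, , drop = FALSE],
                                  leaf_of[as.character(rep$calib)], leaf,
                                  vars_g)
          fit <- fit_sdm(m, train,
                         seed = derive_seed(seed, 100L + n_jobs_run))
          n_jobs_run <- n_jobs_run + 1L
          for (sc in scenarios)
            acc[[sc]] <- acc[[sc]] + predict_suitability(fit, stack_vals[[sc]])
          prev_acc <- prev_acc + train$prevalence
          valid_ix <- match(rep$valid, cells$cell_id)
          s_val <- predict_suitability(fit,
                                       cells_clim[valid_ix, vars_g, drop = FALSE])
          truth_val <- leaf_of[as.character(rep$valid)] == leaf
          tss_r <- tryCatch(
            confusion_metrics(binarize_quiet(s_val, train$prevalence),
                              truth_val)$tss,
            error = function(e) NA_real_)
          tss_acc <- c(tss_acc, tss_r)
        }
        for (sc in scenarios) surf[[m]][[lf]][[sc]] <- acc[[sc]] / mdl$n_reps
        thr[[m]][[lf]] <- prev_acc / mdl$n_reps
        itss[[m]][[lf]] <- mean(tss_acc, na.rm = TRUE)
      }
    }
    fits_summary[[g]] <- list(surfaces = surf, thresholds = thr,
                              internal_tss = itss, leaves = leaves_use,
                              vars = vars_g)
    say("model", "%s: %d leaves x %d methods x %d replicates fitted", g,
        length(leaves_use), length(mdl$methods), mdl$n_reps)
  }

  ## -- evaluate + select ---------------------------------------------------
  metrics_by_gcm <- list(); selected_by_gcm <- list()
  for (g in gcm_ids) {
    fs <- fits_summary[[g]]
    baseline_surfaces <- lapply(fs$surfaces, function(per_leaf)
      lapply(per_leaf, `[[`, "baseline"))
    metrics_by_gcm[[g]] <- external_validate(
      baseline_surfaces, fs$thresholds, cells$cell_id, design$holdout_ids,
      design$sample_ids, partitions[[g]]$assignment$leaf_id)
    metrics_by_gcm[[g]]$gcm <- g
    selected_by_gcm[[g]] <- select_methods(metrics_by_gcm[[g]],
                                           cutoff = mdl$cutoff)
    say("evaluate", "%s: adequate methods: %s", g,
        paste(selected_by_gcm[[g]], collapse = ", "))
  }
  selected <- Reduce(intersect, selected_by_gcm)
  family_methods <- intersect(method_families()[[config$projection$family]],
                              intersect(selected, mdl$methods))
  if (!length(family_methods))
    stop("projection stage: no adequate method in family '",
         config$projection$family, "'; adequate overall: ",
         paste(selected, collapse = ", "))
  say("select", "family '%s' members used for projection: %s",
      config$projection$family, paste(family_methods, collapse = ", "))

  ## -- ensemble + project + aggregate --------------------------------------
  category_bin <- list()    # [[gcm]][[scenario]] cells x categories
  uncertainty <- list()     # [[gcm]][[scenario]]
  ensemble_holdout <- list()
  for (g in gcm_ids) {
    fs <- fits_summary[[g]]
    part <- partitions[[g]]
    leaf_cat <- stats::setNames(part$leaves$predicted_category,
                                part$leaves$leaf_id)
    category_bin[[g]] <- list(); uncertainty[[g]] <- list()
    ens_rows <- list()
    for (sc in scenarios) {
      leaf_bin <- sapply(as.character(fs$leaves), function(lf) {
        members <- sapply(family_methods, function(m)
          fs$surfaces[[m]][[lf]][[sc]])
        w <- vapply(family_methods, function(m) fs$internal_tss[[m]][[lf]],
                    numeric(1))
        ens <- tss_weighted_ensemble(members, w)
        thr <- mean(vapply(family_methods, function(m) fs$thresholds[[m]][[lf]],
                           numeric(1)))
        if (sc == "baseline") {
          hix <- match(design$holdout_ids, cells$cell_id)
          truth_h <- part$assignment$leaf_id[hix] == as_leaf_id(lf)
          cm <- confusion_metrics(binarize_quiet(ens[hix], thr), truth_h)
          ens_rows[[lf]] <<- data.frame(
            gcm = g, leaf = lf, sensitivity = cm$sensitivity,
            specificity = cm$specificity, tss = cm$tss,
            auc = auc_score(ens[hix], truth_h))
        }
        binarize_quiet(ens, thr)
      })
      colnames(leaf_bin) <- as.character(fs$leaves)
      uncertainty[[g]][[sc]] <- uncertainty_map(leaf_bin, cells$area_km2)
      category_bin[[g]][[sc]] <- pad_categories(
        aggregate_leaves(leaf_bin, leaf_cat), native_cats)
    }
    ensemble_holdout[[g]] <- do.call(rbind, ens_rows)
    say("project", "%s: ensembles projected onto %s", g,
        paste(scenarios, collapse = ", "))
  }

  ## -- consensus + refugia -------------------------------------------------
  consensus <- lapply(scenarios, function(sc)
    gcm_consensus(lapply(gcm_ids, function(g) category_bin[[g]][[sc]]),
                  rule = config$projection$consensus))
  names(consensus) <- scenarios
  # Current distribution for the stability comparison: the reclassified
  # (tree) landcover map, which is known, not modeled; cross-GCM consensus.
  classified_bin <- lapply(gcm_ids, function(g) {
    part <- partitions[[g]]
    pad_categories(
      vapply(native_cats, function(k)
        part$assignment$predicted_category == k,
        logical(nrow(cells))), native_cats)
  })
  names(classified_bin) <- gcm_ids
  current_classified <- gcm_consensus(classified_bin,
                                      rule = config$projection$consensus)
  regions <- if (!is.null(config$refugia$regions_file))
    read_regions(config$refugia$regions_file) else
    synthetic_regions(domain, config$refugia$nx, config$refugia$ny)

  refugia_rows <- list(); region_rows <- list()
  stable_pct <- list()
  refuge_maps <- list()
  for (rcp in rcps) {
    refuge <- current_classified & consensus[[rcp]]
    refuge_maps[[rcp]] <- refuge
    stable_pct[[rcp]] <- range_area(rowSums(refuge) > 0, cells$area_km2)$pct
    reg <- refuges_by_region(refuge, regions, cells$lat, cells$lon,
                             cells$area_km2)
    reg$rcp <- rcp
    region_rows[[rcp]] <- reg
    for (k in native_cats) {
      cur <- current_classified[, k]; fut <- consensus[[rcp]][, k]
      area <- range_area(refuge[, k], cells$area_km2)
      cen_c <- range_centroid(cur, cells$lat, cells$lon, cells$area_km2)
      cen_f <- range_centroid(fut, cells$lat, cells$lon, cells$area_km2)
      disp <- displacement(cen_c, cen_f)
      refugia_rows[[paste(rcp, k)]] <- data.frame(
        rcp = rcp, category = k,
        refuge_km2 = area$km2, refuge_pct = area$pct,
        current_km2 = range_area(cur, cells$area_km2)$km2,
        future_km2 = range_area(fut, cells$area_km2)$km2,
        extirpated = cen_f$extirpated,
        centroid_lat_current = cen_c$lat, centroid_lon_current = cen_c$lon,
        centroid_lat_future = cen_f$lat, centroid_lon_future = cen_f$lon,
        displacement_km = disp$km, bearing_deg = disp$bearing_deg,
        jaccard_truth = jaccard(refuge[, k], truth_refuge[[rcp]][, k]))
    }
    say("refugia", "%s: %.1f%% of the domain is stable", rcp,
        stable_pct[[rcp]])
  }
  refugia_table <- do.call(rbind, c(refugia_rows, list(make.row.names = FALSE)))
  region_table <- do.call(rbind, c(region_rows, list(make.row.names = FALSE)))

  registry_obj <- make_job_registry(
    mdl$methods,
    vapply(fits_summary, function(fs) length(fs$leaves), integer(1)),
    mdl$n_reps)

  report <- structure(list(
    config = config, domain = domain, cells = cells,
    truth = list(current = truth_current, refuge = truth_refuge),
    trees = trees, partitions = partitions, design = design,
    registry = registry_obj, metrics = do.call(rbind, metrics_by_gcm),
    selected_methods = selected, family_methods = family_methods,
    ensemble_holdout = do.call(rbind, ensemble_holdout),
    category_bin = category_bin, consensus = consensus,
    current_classified = current_classified,
    uncertainty = uncertainty, refuge_maps = refuge_maps,
    refugia_table = refugia_table, region_table = region_table,
    stable_pct = stable_pct, sensitivity = sens_report,
    log = log), class = "refuge_report")

  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

pad_categories <- function(mat, cats) {
  out <- matrix(FALSE, nrow(mat), length(cats),
                dimnames = list(NULL, cats))
  common <- intersect(colnames(mat), cats)
  out[, common] <- mat[, common]
  out
}

#' @export
print.refuge_report <- function(x, ...) {
  cat("refuge_report\n")
  cat(sprintf("  %d cells; methods projected: %s\n", nrow(x$cells),
              paste(x$family_methods, collapse = ", ")))
  for (rcp in names(x$stable_pct))
    cat(sprintf("  %s: %.1f%% of the domain stable\n", rcp,
                x$stable_pct[[rcp]]))
  invisible(x)
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cells(report$cells, file.path(out_dir, "cells.csv"))
  for (g in names(report$partitions)) {
    utils::write.csv(report$partitions[[g]]$assignment,
                     file.path(out_dir, sprintf("partition_%s.csv", g)),
                     row.names = FALSE)
  }
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$refugia_table, file.path(out_dir, "refugia.csv"),
                   row.names = FALSE)
  utils::write.csv(report$region_table, file.path(out_dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$registry$jobs, file.path(out_dir, "registry.csv"),
                   row.names = FALSE)
  for (rcp in names(report$refuge_maps)) {
    for (k in colnames(report$refuge_maps[[rcp]])) {
      write_raster(as.numeric(report$refuge_maps[[rcp]][, k]),
                   report$domain,
                   file.path(out_dir, sprintf("refuge_%s_%s.asc",
                                              gsub("[^A-Za-z0-9.]", "", rcp), k)))
    }
  }
  summary <- list(
    stable_pct = report$stable_pct,
    selected_methods = report$selected_methods,
    family_methods = report$family_methods,
    n_fit_jobs = report$registry$n_fit_jobs,
    n_surfaces = report$registry$n_surfaces)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(report$config, file.path(out_dir, "config.yaml"))
  writeLines(vapply(report$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}
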