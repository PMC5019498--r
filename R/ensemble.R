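# Replicate/sampling design, TSS-weighted ensembles, projection onto future
# climate, leaf-to-category aggregation, and cross-GCM consensus.

#' Replicate sampling design
#'
#' Draws the modeling sample (a uniform random `sample_frac` of all cells,
#' without replacement) and, for each replicate, splits it into calibration
#' and validation parts. Calibration size is `round(calib_frac * n_sample)`
#' (R's round-half-to-even), the remainder validates. Fully reproducible
#' from the seed.
#'
#' @param cell_ids All modeled cell ids.
#' @param sample_frac Fraction of cells in the modeling sample (default 0.25).
#' @param calib_frac Calibration fraction within the sample (default 0.75).
#' @param n_reps Number of replicates (default 10).
#' @param seed Seed.
#' @return Object of class `replicate_design`: `sample_ids`, `holdout_ids`,
#'   and `replicates` (list of `list(calib =, valid =)`).
#' @export
make_design <- function(cell_ids, sample_frac = 0.25, calib_frac = 0.75,
                        n_reps = 10, seed = 1) {
  if (sample_frac <= 0 || sample_frac > 1 || calib_frac <= 0 || calib_frac >= 1)
    stop("sample_frac must be in (0,1] and calib_frac in (0,1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(as.integer(seed))
  n_sample <- round(sample_frac * length(cell_ids))
  sample_ids <- if (sample_frac == 1) cell_ids else
    sort(sample(cell_ids, n_sample))
  n_calib <- round(calib_frac * length(sample_ids))
  replicates <- lapply(seq_len(n_reps), function(r) {
    calib <- sort(sample(sample_ids, n_calib))
    list(calib = calib, valid = setdiff(sample_ids, calib))
  })
  structure(list(sample_ids = sample_ids,
                 holdout_ids = setdiff(cell_ids, sample_ids),
                 replicates = replicates,
                 sample_frac = sample_frac, calib_frac = calib_frac,
                 n_reps = n_reps, seed = seed),
            class = "replicate_design")
}

#' @export
print.replicate_design <- function(x, ...) {
  cat(sprintf(
    "replicate_design: %d sample / %d holdout cells, %d replicates (%d/%d)\n",
    length(x$sample_ids), length(x$holdout_ids), x$n_reps,
    length(x$replicates[[1]]$calib), length(x$replicates[[1]]$valid)))
  invisible(x)
}

#' Enumerate the fit-job registry
#'
#' One fit job per (GCM, leaf, method, replicate); one averaged surface per
#' (GCM, leaf, method). With M methods, R replicates and L leaves in total
#' across the GCMs the registry holds exactly M*R*L fit jobs and M*L
#' averaged surfaces.
#'
#' @param method_ids Method (or ensemble-slot) labels.
#' @param leaves_per_gcm Named integer vector: number of leaves per GCM.
#' @param n_reps Replicates per fit.
#' @return Object of class `job_registry`: `jobs` and `surfaces` data
#'   frames plus `n_fit_jobs` and `n_surfaces` counts.
#' @export
make_job_registry <- function(method_ids, leaves_per_gcm, n_reps = 10) {
  if (is.null(names(leaves_per_gcm)))
    names(leaves_per_gcm) <- paste0("gcm", seq_along(leaves_per_gcm))
  jobs <- do.call(rbind, lapply(names(leaves_per_gcm), function(g) {
    expand.grid(gcm = g, leaf = seq_len(leaves_per_gcm[[g]]),
                method = method_ids, replicate = seq_len(n_reps),
                stringsAsFactors = FALSE)
  }))
  surfaces <- unique(jobs[, c("gcm", "leaf", "method")])
  rownames(jobs) <- rownames(surfaces) <- NULL
  structure(list(jobs = jobs, surfaces = surfaces,
                 n_fit_jobs = nrow(jobs), n_surfaces = nrow(surfaces)),
            class = "job_registry")
}

#' TSS-weighted ensemble of suitability surfaces
#'
#' Weighted average of member surfaces with weights equal to each member's
#' internal-validation TSS; negative TSS clamps to weight 0 (the member is
#' excluded rather than contributing a negative weight).
#'
#' @param surfaces Numeric cells x members matrix (or list of equal-length
#'   vectors).
#' @param tss_weights Numeric vector of member TSS values.
#' @return Combined suitability vector; an error if every weight clamps
#'   to 0.
#' @export
tss_weighted_ensemble <- function(surfaces, tss_weights) {
  if (is.list(surfaces)) surfaces <- do.call(cbind, surfaces)
  surfaces <- as.matrix(surfaces)
  if (ncol(surfaces) != length(tss_weights))
    stop("one weight per member surface is required")
  w <- pmax(tss_weights, 0)
  if (sum(w) <= 0) stop("all ensemble weights are <= 0")
  drop(surfaces %*% w) / sum(w)
}

#' Aggregate leaf presences into category presences
#'
#' A category is present wherever any of its leaves is present (cellwise
#' union), expressing the totality of the category's range.
#'
#' @param leaf_binaries Logical cells x leaves matrix with leaf ids as
#'   column names.
#' @param leaf_category Named vector mapping leaf id -> category.
#' @return Logical cells x categories matrix.
#' @export
aggregate_leaves <- function(leaf_binaries, leaf_category) {
  leaf_binaries <- as.matrix(leaf_binaries)
  leaves <- colnames(leaf_binaries)
  if (is.null(leaves)) stop("leaf_binaries needs leaf ids as column names")
  unmapped <- setdiff(leaves, names(leaf_category))
  if (length(unmapped))
    stop("leaf(s) without a category mapping: ",
         paste(unmapped, collapse = ", "))
  cats <- sort(unique(as.character(leaf_category[leaves])))
  out <- vapply(cats, function(k) {
    members <- leaves[as.character(leaf_category[leaves]) == k]
    rowSums(leaf_binaries[, members, drop = FALSE]) > 0
  }, logical(nrow(leaf_binaries)))
  colnames(out) <- cats
  out
}

#' Cross-GCM consensus of category ranges
#'
#' The primary rule is unanimity: a category is retained in a cell only
#' where every climate model predicts it (cellwise AND), which is where the
#' predictions converge. A majority rule is available behind the flag.
#'
#' @param category_binaries_by_gcm List (one element per GCM) of logical
#'   cells x categories matrices with identical column sets.
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @return Logical cells x categories consensus matrix.
#' @export
gcm_consensus <- function(category_binaries_by_gcm,
                          rule = c("unanimity", "majority")) {
  rule <- match.arg(rule)
  if (length(category_binaries_by_gcm) < 2)
    stop("consensus needs at least 2 GCMs")
  cats <- colnames(category_binaries_by_gcm[[1]])
  for (m in category_binaries_by_gcm) {
    if (!identical(colnames(m), cats))
      stop("category missing or reordered for one of the GCMs")
  }
  acc <- Reduce(`+`, lapply(category_binaries_by_gcm,
                            function(m) 1 * as.matrix(m)))
  n <- length(category_binaries_by_gcm)
  out <- if (rule == "unanimity") acc == n else acc > n / 2
  colnames(out) <- cats
  out
}
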