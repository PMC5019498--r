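# Geographic distribution models over climate, fitted on leaf
# presence/absence. Absences are true absences (cells of other leaves): the
# full landcover distribution is known, which is what makes this design
# bias-free. Every method returns a suitability in [0,1] for any climate
# vector.

#' Available distribution-model identifiers
#'
#' The nine supported method ids, in family order: envelope/distance
#' (`bioclim`, `gower`, `mahalanobis`), statistical (`glm`, `gam`, `mars`)
#' and machine learning (`maxent_like`, `garp_like`, `rf`).
#' @export
SDM_METHODS <- c("bioclim", "gower", "mahalanobis", "glm", "gam", "mars",
                 "maxent_like", "garp_like", "rf")

#' Build a presence/absence training set for one leaf
#'
#' @param cells Cell table (rows = candidate cells, e.g. a calibration split).
#' @param leaf_ids Leaf assignment for `cells` (same length).
#' @param leaf The presence leaf.
#' @param vars Climate variables to use (typically [tree_variables()] of the
#'   pruned tree).
#' @return Object of class `sdm_train`: `x` (matrix), `y` (0/1), `prevalence`.
#' @export
make_train_set <- function(cells, leaf_ids, leaf, vars) {
  stopifnot(length(leaf_ids) == nrow(cells))
  missing_vars <- setdiff(vars, names(cells))
  if (length(missing_vars))
    stop("cells lack variable(s): ", paste(missing_vars, collapse = ", "))
  y <- as.integer(leaf_ids == leaf)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("training set needs both presences and absences for leaf ", leaf)
  structure(list(x = as.matrix(cells[, vars, drop = FALSE]), y = y,
                 vars = vars, leaf = leaf,
                 prevalence = mean(y)), class = "sdm_train")
}

#' Fit a distribution model
#'
#' Methods: `bioclim` (percentile envelope), `gower` (range-normalised
#' nearest-presence distance), `mahalanobis` (distance to the presence
#' centroid mapped through the chi-square survival function), `glm`
#' (logistic, linear + quadratic terms), `gam` (additive logistic with
#' smooth terms), `mars` (adaptive hinge basis with GCV pruning under a
#' logistic link), `maxent_like` (penalised logistic on hinge + quadratic
#' features against a background sample; simplified analogue), `garp_like`
#' (genetic algorithm over conjunctive envelope rules; simplified analogue),
#' and `rf` (bagged classification trees, suitability = vote fraction).
#'
#' @param method One of [SDM_METHODS].
#' @param train An `sdm_train` from [make_train_set()].
#' @param hyper Optional list of method hyperparameters (see the methods
#'   vignette for names and defaults).
#' @param seed Seed for the stochastic methods (`maxent_like` fold
#'   assignment, `garp_like`, `rf`).
#' @return Object of class `sdm_fit`.
#' @export
fit_sdm <- function(method, train, hyper = list(), seed = 1) {
  method <- match.arg(method, SDM_METHODS)
  stopifnot(inherits(train, "sdm_train"))
  if (sum(train$y) < 5) stop("need at least 5 presences, got ", sum(train$y))
  model <- switch(method,
    bioclim = fit_bioclim(train, hyper),
    gower = fit_gower(train, hyper),
    mahalanobis = fit_mahal(train, hyper),
    glm = fit_glm_sdm(train, hyper),
    gam = fit_gam_sdm(train, hyper),
    mars = fit_mars_sdm(train, hyper),
    maxent_like = fit_maxent_like(train, hyper, seed),
    garp_like = fit_garp_like(train, hyper, seed),
    rf = fit_rf_sdm(train, hyper, seed))
  structure(list(method = method, vars = train$vars, leaf = train$leaf,
                 prevalence = train$prevalence, model = model),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit: %s on %d variable(s), training prevalence %.3f\n",
              x$method, length(x$vars), x$prevalence))
  invisible(x)
}

#' Predict continuous suitability
#'
#' @param fit An `sdm_fit`.
#' @param newdata A `climate_stack`, data frame or matrix containing the
#'   fit's variables (an error names any missing one).
#' @return Numeric suitability in \[0,1\], one value per row/cell.
#' @export
predict_suitability <- function(fit, newdata) {
  stopifnot(inherits(fit, "sdm_fit"))
  if (inherits(newdata, "climate_stack")) newdata <- newdata$values
  newdata <- as.matrix(as.data.frame(newdata)[, , drop = FALSE])
  missing_vars <- setdiff(fit$vars, colnames(newdata))
  if (length(missing_vars))
    stop("newdata lacks variable(s): ", paste(missing_vars, collapse = ", "))
  x <- newdata[, fit$vars, drop = FALSE]
  s <- switch(fit$method,
    bioclim = predict_bioclim(fit$model, x),
    gower = predict_gower(fit$model, x),
    mahalanobis = predict_mahal(fit$model, x),
    glm = predict_glm_sdm(fit$model, x),
    gam = predict_gam_sdm(fit$model, x),
    mars = predict_mars_sdm(fit$model, x),
    maxent_like = predict_maxent_like(fit$model, x),
    garp_like = predict_garp_like(fit$model, x),
    rf = predict_rf_sdm(fit$model, x))
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Convert suitability to binary presence at the prevalence threshold
#'
#' A cell is predicted present when its suitability is greater than or
#' *equal to* the threshold (the >= boundary is part of the contract).
#'
#' @param suitability Numeric vector in \[0,1\].
#' @param threshold Cutoff in (0,1); conventionally the training prevalence.
#' @return Logical vector; an all-absent result is allowed (a message is
#'   emitted).
#' @export
binarize <- function(suitability, threshold) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  out <- suitability >= threshold
  if (!any(out)) message("binarize: empty predicted range")
  out
}

## ---- bioclim -------------------------------------------------------------

fit_bioclim <- function(train, hyper) {
  trim <- hyper$trim %||% 0
  p <- train$x[train$y == 1, , drop = FALSE]
  list(presence = p, trim = trim,
       lo = apply(p, 2, stats::quantile, probs = trim),
       hi = apply(p, 2, stats::quantile, probs = 1 - trim))
}

predict_bioclim <- function(model, x) {
  n <- nrow(x)
  smin <- rep(1, n)
  for (j in seq_len(ncol(x))) {
    f <- stats::ecdf(model$presence[, j])
    sj <- 1 - 2 * abs(f(x[, j]) - 0.5)
    sj[x[, j] < model$lo[j] | x[, j] > model$hi[j]] <- 0
    smin <- pmin(smin, sj)
  }
  smin
}

## ---- gower (DOMAIN-style nearest presence) -------------------------------

fit_gower <- function(train, hyper) {
  p <- train$x[train$y == 1, , drop = FALSE]
  rng <- apply(p, 2, function(v) diff(range(v)))
  rng[rng == 0] <- NA  # zero-range variable: exact match or full mismatch
  list(presence = p, range = rng)
}

predict_gower <- function(model, x) {
  p <- model$presence
  n <- nrow(x); m <- nrow(p); k <- ncol(p)
  best <- rep(Inf, n)
  for (i in seq_len(m)) {
    diffs <- abs(x - matrix(p[i, ], n, k, byrow = TRUE))
    scaled <- sweep(diffs, 2, model$range, "/")
    scaled[, is.na(model$range)] <- ifelse(
      diffs[, is.na(model$range), drop = FALSE] == 0, 0, 1)
    best <- pmin(best, rowMeans(scaled))
  }
  pmin(pmax(1 - best, 0), 1)
}

## ---- mahalanobis ---------------------------------------------------------

fit_mahal <- function(train, hyper) {
  ridge <- hyper$ridge %||% "auto"
  p <- train$x[train$y == 1, , drop = FALSE]
  mu <- colMeans(p)
  S <- stats::cov(p)
  lambda <- 0
  if (identical(ridge, "auto")) {
    if (rcond(S) < 1e-10) lambda <- 1e-6 * mean(diag(S))
  } else lambda <- as.numeric(ridge)
  if (lambda > 0) S <- S + diag(lambda, ncol(S))
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("presence covariance is singular; set hyper$ridge to regularise")
  list(mu = mu, S = S, df = ncol(p))
}

predict_mahal <- function(model, x) {
  d2 <- stats::mahalanobis(x, model$mu, model$S)
  stats::pchisq(d2, df = model$df, lower.tail = FALSE)
}

## ---- glm -----------------------------------------------------------------

quad_formula <- function(vars, quadratic = TRUE) {
  terms <- vars
  if (quadratic) terms <- c(terms, sprintf("I(%s^2)", vars))
  stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
}

fit_glm_sdm <- function(train, hyper) {
  quadratic <- hyper$quadratic %||% TRUE
  dat <- as.data.frame(train$x)
  dat$.y <- train$y
  fit <- suppressWarnings(
    stats::glm(quad_formula(train$vars, quadratic), data = dat,
               family = stats::binomial()))
  list(fit = fit)
}

predict_glm_sdm <- function(model, x) {
  suppressWarnings(
    stats::predict(model$fit, newdata = as.data.frame(x), type = "response"))
}

## ---- gam -----------------------------------------------------------------

fit_gam_sdm <- function(train, hyper) {
  k <- hyper$k %||% 5
  dat <- as.data.frame(train$x)
  dat$.y <- train$y
  # parametric quadratic + penalized smooth per variable: the quadratic
  # logistic model is an exact submodel at any penalty, so the additive fit
  # never has higher training deviance than the glm method
  terms <- vapply(train$vars, function(v) {
    nu <- length(unique(dat[[v]]))
    if (nu < 4) v else
      sprintf("%s + I(%s^2) + s(%s, k = %d)", v, v, v, min(k, nu - 1))
  }, character(1))
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(
    mgcv::gam(form, data = dat, family = stats::binomial()))
  list(fit = fit)
}

predict_gam_sdm <- function(model, x) {
  suppressWarnings(as.numeric(
    mgcv::predict.gam(model$fit, newdata = as.data.frame(x),
                      type = "response")))
}

## ---- mars (adaptive hinge regression, GCV-pruned, logistic link) ---------

mars_basis <- function(x, terms) {
  if (!length(terms)) return(matrix(1, nrow(x), 1))
  cols <- lapply(terms, function(tm) {
    v <- x[, tm$var]
    if (tm$sign > 0) pmax(v - tm$knot, 0) else pmax(tm$knot - v, 0)
  })
  cbind(1, do.call(cbind, cols))
}

mars_rss <- function(B, y) {
  fit <- stats::lm.fit(B, y)
  sum(fit$residuals^2)
}

fit_mars_sdm <- function(train, hyper) {
  max_terms <- hyper$max_terms %||% 21
  n_knots <- hyper$n_knots %||% 15
  penalty <- hyper$penalty %||% 3
  x <- train$x; y <- train$y; n <- length(y)
  knots <- lapply(train$vars, function(v)
    unique(stats::quantile(x[, v], probs = seq(0.05, 0.95,
                                               length.out = n_knots))))
  names(knots) <- train$vars

  terms <- list()
  best_rss <- mars_rss(matrix(1, n, 1), y)
  repeat {
    room <- max_terms - length(terms)
    if (room <= 0) break
    cand_best <- NULL; cand_rss <- best_rss - 1e-10
    for (v in train$vars) for (t in knots[[v]]) {
      pair <- list(list(var = v, knot = t, sign = 1),
                   list(var = v, knot = t, sign = -1))
      adds <- if (room >= 2) list(pair, pair[1], pair[2]) else
        list(pair[1], pair[2])
      for (add in adds) {
        B <- mars_basis(x, c(terms, add))
        r <- mars_rss(B, y)
        if (r < cand_rss) { cand_rss <- r; cand_best <- add }
      }
    }
    if (is.null(cand_best)) break
    terms <- c(terms, cand_best)
    best_rss <- cand_rss
  }

  # backward pruning by generalized cross-validation
  gcv <- function(tms) {
    B <- mars_basis(x, tms)
    M <- ncol(B)
    C <- M + penalty * (M - 1) / 2
    if (C >= n) return(Inf)
    (mars_rss(B, y) / n) / (1 - C / n)^2
  }
  best_terms <- terms
  best_gcv <- gcv(terms)
  cur <- terms
  while (length(cur) > 0) {
    scores <- vapply(seq_along(cur), function(i) gcv(cur[-i]), numeric(1))
    drop_i <- which.min(scores)
    cur <- cur[-drop_i]
    if (scores[drop_i] < best_gcv) { best_gcv <- scores[drop_i]; best_terms <- cur }
  }

  B <- mars_basis(x, best_terms)
  glm_fit <- tryCatch(
    suppressWarnings(stats::glm.fit(B, y, family = stats::binomial())),
    error = function(e) NULL)
  coefs <- if (!is.null(glm_fit) && all(is.finite(glm_fit$coefficients)))
    list(type = "logistic", beta = glm_fit$coefficients) else
    list(type = "linear", beta = stats::lm.fit(B, y)$coefficients)
  coefs$beta[is.na(coefs$beta)] <- 0
  list(terms = best_terms, coefs = coefs)
}

predict_mars_sdm <- function(model, x) {
  B <- mars_basis(x, model$terms)
  eta <- drop(B %*% model$coefs$beta)
  if (model$coefs$type == "logistic") stats::plogis(eta) else
    pmin(pmax(eta, 0), 1)
}

## ---- maxent-like (penalised logistic on hinge+quadratic features) --------

maxent_features <- function(x, vars, knots) {
  feats <- list(x, x^2)
  for (v in vars) for (t in knots[[v]]) {
    feats <- c(feats, list(pmax(x[, v] - t, 0)))
  }
  out <- do.call(cbind, feats)
  colnames(out) <- NULL
  out
}

fit_maxent_like <- function(train, hyper, seed) {
  n_knots <- hyper$n_knots %||% 5
  x <- train$x
  knots <- lapply(train$vars, function(v)
    unique(stats::quantile(x[, v], probs = seq(0.15, 0.85,
                                               length.out = n_knots))))
  names(knots) <- train$vars
  # background = all sampled cells; presences weighted to balance
  feats <- maxent_features(x, train$vars, knots)
  y <- train$y
  w <- ifelse(y == 1, 1, sum(y) / sum(y == 0))
  set.seed(as.integer(seed))
  foldid <- sample(rep(1:5, length.out = length(y)))
  cv <- suppressWarnings(
    glmnet::cv.glmnet(feats, y, family = "binomial", weights = w,
                      alpha = 1, foldid = foldid, standardize = TRUE))
  list(cv = cv, knots = knots, vars = train$vars)
}

predict_maxent_like <- function(model, x) {
  feats <- maxent_features(x, model$vars, model$knots)
  as.numeric(stats::predict(model$cv, newx = feats, s = "lambda.1se",
                            type = "response"))
}

## ---- garp-like (genetic algorithm over conjunctive envelope rules) -------

garp_predict_rules <- function(rules, x) {
  # presence if any rule's envelope contains the point
  hit <- rep(FALSE, nrow(x))
  for (r in rules) {
    ok <- rep(TRUE, nrow(x))
    for (j in seq_along(r$vars)) {
      v <- x[, r$vars[j]]
      ok <- ok & v >= r$lo[j] & v <= r$hi[j]
    }
    hit <- hit | ok
  }
  hit
}

garp_fitness <- function(rules, x, y) {
  pred <- garp_predict_rules(rules, x)
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  sens + spec - 1
}

garp_random_rule <- function(x, y, vars) {
  pres_ix <- which(y == 1)
  seedpt <- x[sample(pres_ix, 1), ]
  use <- sample(vars, sample(seq_along(vars), 1))
  widths <- vapply(use, function(v) diff(range(x[, v])) *
                     stats::runif(1, 0.05, 0.5), numeric(1))
  list(vars = use, lo = seedpt[use] - widths, hi = seedpt[use] + widths)
}

fit_garp_like <- function(train, hyper, seed) {
  pop_size <- hyper$pop_size %||% 30
  n_gens <- hyper$n_gens %||% 25
  n_rules <- hyper$n_rules %||% 4
  top_k <- hyper$top_k %||% 10
  x <- train$x; y <- train$y; vars <- train$vars
  set.seed(as.integer(seed))
  new_ind <- function() lapply(seq_len(n_rules), function(i)
    garp_random_rule(x, y, vars))
  pop <- lapply(seq_len(pop_size), function(i) new_ind())
  fitness <- vapply(pop, garp_fitness, numeric(1), x = x, y = y)
  for (g in seq_len(n_gens)) {
    nextgen <- pop[order(fitness, decreasing = TRUE)[1:2]]  # elitism
    while (length(nextgen) < pop_size) {
      pick <- function() {  # tournament of 3
        ix <- sample.int(pop_size, 3)
        pop[[ix[which.max(fitness[ix])]]]
      }
      a <- pick(); b <- pick()
      cut <- sample.int(n_rules - 1, 1)
      child <- c(a[seq_len(cut)], b[(cut + 1):n_rules])
      if (stats::runif(1) < 0.4) {  # mutate one rule
        i <- sample.int(n_rules, 1)
        if (stats::runif(1) < 0.5) {
          child[[i]] <- garp_random_rule(x, y, vars)
        } else {
          r <- child[[i]]
          j <- sample(seq_along(r$vars), 1)
          w <- diff(range(x[, r$vars[j]]))
          r$lo[j] <- r$lo[j] + stats::rnorm(1, 0, 0.1 * w)
          r$hi[j] <- max(r$lo[j], r$hi[j] + stats::rnorm(1, 0, 0.1 * w))
          child[[i]] <- r
        }
      }
      nextgen <- c(nextgen, list(child))
    }
    pop <- nextgen
    fitness <- vapply(pop, garp_fitness, numeric(1), x = x, y = y)
  }
  keep <- order(fitness, decreasing = TRUE)[seq_len(min(top_k, pop_size))]
  list(ensemble = pop[keep])
}

predict_garp_like <- function(model, x) {
  votes <- vapply(model$ensemble, function(ind)
    as.numeric(garp_predict_rules(ind, x)), numeric(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  rowMeans(votes)
}

## ---- rf (bagged classification trees, vote fraction) ---------------------

fit_rf_sdm <- function(train, hyper, seed) {
  n_trees <- hyper$n_trees %||% 200
  x <- as.data.frame(train$x); y <- factor(train$y, levels = c(0, 1))
  p <- length(train$vars)
  m_try <- hyper$m_try %||% max(1, floor(sqrt(p)))
  set.seed(as.integer(seed))
  trees <- vector("list", n_trees)
  inbag <- matrix(FALSE, nrow(x), n_trees)
  for (t in seq_len(n_trees)) {
    ix <- sample.int(nrow(x), replace = TRUE)
    inbag[unique(ix), t] <- TRUE
    vsub <- sample(train$vars, m_try)
    dat <- x[ix, vsub, drop = FALSE]
    dat$.y <- y[ix]
    trees[[t]] <- list(
      fit = rpart::rpart(.y ~ ., data = dat, method = "class",
                         control = rpart::rpart.control(
                           minsplit = 10, cp = 0.005, xval = 0,
                           maxcompete = 0, maxsurrogate = 0)),
      vars = vsub)
  }
  # out-of-bag vote accuracy
  oob_votes <- matrix(NA_real_, nrow(x), n_trees)
  for (t in seq_len(n_trees)) {
    oob <- !inbag[, t]
    if (!any(oob)) next
    pr <- stats::predict(trees[[t]]$fit,
                         newdata = x[oob, trees[[t]]$vars, drop = FALSE],
                         type = "class")
    oob_votes[oob, t] <- as.numeric(as.character(pr))
  }
  vote_frac <- rowMeans(oob_votes, na.rm = TRUE)
  covered <- !is.nan(vote_frac)
  oob_accuracy <- mean((vote_frac[covered] >= 0.5) ==
                         (train$y[covered] == 1))
  list(trees = trees, inbag = inbag, oob_accuracy = oob_accuracy,
       oob_votes = oob_votes, y = train$y)
}

predict_rf_sdm <- function(model, x) {
  xd <- as.data.frame(x)
  votes <- matrix(0, nrow(xd), length(model$trees))
  for (t in seq_along(model$trees)) {
    pr <- stats::predict(model$trees[[t]]$fit,
                         newdata = xd[, model$trees[[t]]$vars, drop = FALSE],
                         type = "class")
    votes[, t] <- as.numeric(as.character(pr))
  }
  rowMeans(votes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
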