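test_that("envelope and distance models honor their closed-form anchors", {
  x <- cbind(bio1 = c(1:10, 30:49), bio2 = c(21:30, 50:69))
  train <- make_train_set(as.data.frame(x), rep(c(1, 2), c(10, 20)), 1,
                          c("bio1", "bio2"))
  # mahalanobis: query at the presence mean -> distance 0 -> suitability 1
  fm <- fit_sdm("mahalanobis", train)
  mu <- colMeans(x[1:10, ])
  expect_equal(predict_suitability(fm, t(as.matrix(mu))), 1)
  # gower: query equal to a presence -> distance 0 -> suitability 1
  fg <- fit_sdm("gower", train)
  expect_equal(predict_suitability(fg, x[3, , drop = FALSE]), 1)
  # bioclim: below a variable's presence minimum -> 0; median percentile -> 1
  fb <- fit_sdm("bioclim", train)
  expect_equal(predict_suitability(fb, cbind(bio1 = 0.5, bio2 = 25)), 0)
  expect_equal(predict_suitability(fb, cbind(bio1 = 5, bio2 = 25)), 1)
})

test_that("envelope and distance models are invariant to presence record order", {
  set.seed(3)
  x <- matrix(stats::rnorm(60 * 3), 60,
              dimnames = list(NULL, c("bio1", "bio2", "bio3")))
  y <- rep(c(1, 2), each = 30)
  q <- matrix(stats::rnorm(15 * 3), 15,
              dimnames = list(NULL, c("bio1", "bio2", "bio3")))
  perm <- c(sample(30), 31:60)
  for (m in c("bioclim", "gower", "mahalanobis")) {
    f1 <- fit_sdm(m, make_train_set(as.data.frame(x), y, 1,
                                    colnames(x)))
    f2 <- fit_sdm(m, make_train_set(as.data.frame(x[perm, ]), y[perm], 1,
                                    colnames(x)))
    expect_equal(predict_suitability(f1, q), predict_suitability(f2, q),
                 tolerance = 1e-12)
  }
})

test_that("mahalanobis suitability is invariant under invertible affine maps", {
  set.seed(4)
  x <- matrix(stats::rnorm(80 * 2), 80, dimnames = list(NULL, c("bio1", "bio2")))
  y <- rep(c(1, 2), each = 40)
  q <- matrix(stats::rnorm(10 * 2), 10, dimnames = list(NULL, c("bio1", "bio2")))
  A <- matrix(c(2, 0.5, -1, 3), 2)
  b <- c(5, -7)
  xt <- sweep(x %*% A, 2, b, "+"); colnames(xt) <- colnames(x)
  qt <- sweep(q %*% A, 2, b, "+"); colnames(qt) <- colnames(q)
  f1 <- fit_sdm("mahalanobis", make_train_set(as.data.frame(x), y, 1,
                                              colnames(x)),
                hyper = list(ridge = 0))
  f2 <- fit_sdm("mahalanobis", make_train_set(as.data.frame(xt), y, 1,
                                              colnames(x)),
                hyper = list(ridge = 0))
  expect_equal(predict_suitability(f1, q), predict_suitability(f2, qt),
               tolerance = 1e-8)
})

test_that("every method returns suitabilities inside [0,1] on random data", {
  set.seed(11)
  train <- box_train(n = 150)
  q <- matrix(stats::runif(400, 15, 32), 200,
              dimnames = list(NULL, c("bio1", "bio2")))
  for (m in SDM_METHODS) {
    f <- fit_sdm(m, train, seed = 2)
    s <- predict_suitability(f, q)
    expect_length(s, 200)
    expect_true(all(s >= 0 & s <= 1), info = m)
  }
  few <- make_train_set(data.frame(bio1 = 1:10, bio2 = 1:10),
                        c(1, 1, 1, rep(2, 7)), 1, c("bio1", "bio2"))
  expect_error(fit_sdm("glm", few), "5 presences")
})

test_that("the additive model nests the quadratic logistic fit in training deviance", {
  train <- box_train(n = 200, seed = 6)  # box response: genuinely nonlinear
  fg <- fit_sdm("glm", train)
  fa <- fit_sdm("gam", train)
  expect_lte(fa$model$fit$deviance, fg$model$fit$deviance + 1e-8)
})

test_that("single-term hinge selection matches brute-force enumeration", {
  set.seed(12)
  x <- matrix(sort(stats::runif(40, 0, 10)), 40, dimnames = list(NULL, "bio1"))
  y <- as.numeric(x[, 1] > 6) + stats::rnorm(40, 0, 0.05)
  train <- structure(list(x = x, y = y, vars = "bio1", leaf = 1,
                          prevalence = mean(y > 0.5)), class = "sdm_train")
  fit <- landrefugia:::fit_mars_sdm(train, list(max_terms = 1, n_knots = 15))
  expect_length(fit$terms, 1)
  # oracle: enumerate every (knot, sign) hinge on the same candidate grid
  knots <- unique(stats::quantile(x[, 1], probs = seq(0.05, 0.95,
                                                      length.out = 15)))
  best <- Inf; best_term <- NULL
  for (t in knots) for (sg in c(1, -1)) {
    h <- if (sg > 0) pmax(x[, 1] - t, 0) else pmax(t - x[, 1], 0)
    rss <- sum(stats::lm.fit(cbind(1, h), y)$residuals^2)
    if (rss < best) { best <- rss; best_term <- list(knot = t, sign = sg) }
  }
  expect_equal(fit$terms[[1]]$knot, best_term$knot, ignore_attr = TRUE)
  expect_equal(fit$terms[[1]]$sign, best_term$sign)
})

test_that("bagged-tree out-of-bag accuracy matches an independent vote recount", {
  train <- box_train(n = 150, seed = 8)
  fit <- fit_sdm("rf", train, hyper = list(n_trees = 50), seed = 5)
  model <- fit$model
  votes <- matrix(NA_real_, nrow(train$x), length(model$trees))
  for (t in seq_along(model$trees)) {
    oob <- !model$inbag[, t]
    pr <- stats::predict(model$trees[[t]]$fit,
                         newdata = as.data.frame(train$x)[oob,
                                                          model$trees[[t]]$vars,
                                                          drop = FALSE],
                         type = "class")
    votes[oob, t] <- as.numeric(as.character(pr))
  }
  frac <- rowMeans(votes, na.rm = TRUE)
  covered <- !is.nan(frac)
  acc <- mean((frac[covered] >= 0.5) == (train$y[covered] == 1))
  expect_equal(model$oob_accuracy, acc)
})

test_that("binarize applies the >= rule; predictions check their inputs", {
  expect_true(binarize(0.31, 30 / 100))
  expect_true(binarize(0.3, 0.3))       # boundary: >= means present
  expect_false(binarize(0.29, 0.3))
  expect_message(out <- binarize(c(0.1, 0.2), 0.5), "empty")
  expect_identical(out, c(FALSE, FALSE))
  expect_error(binarize(0.5, 0), "threshold")
  expect_error(binarize(0.5, 1), "threshold")

  train <- box_train()
  f <- fit_sdm("glm", train)
  expect_error(predict_suitability(f, data.frame(bio1 = 1)), "bio2")

  # a monotone one-variable logistic is monotone in that variable
  set.seed(13)
  x1 <- data.frame(bio1 = stats::runif(100, 0, 10),
                   bio2 = stats::runif(100, 0, 1))
  y1 <- ifelse(x1$bio1 > 5, 1L, 2L)
  fmono <- fit_sdm("glm", make_train_set(x1, y1, 1, c("bio1", "bio2")),
                   hyper = list(quadratic = FALSE))
  grid <- data.frame(bio1 = seq(0, 10, 0.5), bio2 = 0.5)
  expect_true(all(diff(predict_suitability(fmono, grid)) >= -1e-10))
})

test_that("predictions translate with the climate by the analytic boundary displacement", {
  w <- noiseless_world()
  rules <- rule_set(list(list(category = "mid",
                              conditions = list(
                                list(var = "bio1", op = ">", value = 22),
                                list(var = "bio1", op = "<=", value = 25)))),
                    default_category = "other")
  lc <- generate_landcover(w$stack, rules)
  train <- make_train_set(w$cells_clim, ifelse(lc == "mid", 1, 2), 1, "bio1")
  f <- fit_sdm("glm", train)
  s_base <- predict_suitability(f, w$stack)
  # +0.45 degC on bio1 (slope 0.45/deg, 0.5-deg cells) = exactly 2 rows
  fut <- generate_climate(w$domain,
                          scenario_spec("g", "RCP4.5", d_temp = 0.45,
                                        d_prec = 0),
                          noise_sd = 0, seed = 1)
  s_fut <- predict_suitability(f, fut)
  n_lat <- w$domain$n_lat
  m_base <- matrix(s_base, n_lat, byrow = TRUE)
  m_fut <- matrix(s_fut, n_lat, byrow = TRUE)
  # future row r+2 sees the climate that baseline row r saw
  expect_equal(m_fut[3:n_lat, ], m_base[1:(n_lat - 2), ], tolerance = 1e-10)
})
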