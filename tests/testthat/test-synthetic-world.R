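test_that("zero-noise climate equals the closed-form gradient and scenario shifts are exactly additive", {
  d <- domain_spec(lat_min = -10, lat_max = 0, lon_min = -60, lon_max = -52,
                   cell_size = 1)
  cc <- cell_centers(d)
  base <- scenario_spec("g", "baseline", d_temp = 1.5, d_prec = -100)
  st0 <- generate_climate(d, base, noise_sd = 0, seed = 3)
  vars <- climate_variables()
  for (j in c(1, 5, 12, 19)) {
    coord <- if (vars$kind[j] == "temperature") cc$lat else cc$lon
    expect_equal(st0$values[, vars$variable[j]],
                 vars$base[j] + vars$slope[j] * coord)
  }
  expect_true(all(scenario_shift(base) == 0))

  rcp45 <- scenario_spec("g", "RCP4.5", d_temp = 1.5, d_prec = -100)
  rcp85 <- scenario_spec("g", "RCP8.5", d_temp = 1.5, d_prec = -100)
  s45 <- generate_climate(d, rcp45, noise_sd = c(0.2, 15), seed = 3)
  s85 <- generate_climate(d, rcp85, noise_sd = c(0.2, 15), seed = 3)
  sb <- generate_climate(d, base, noise_sd = c(0.2, 15), seed = 3)
  # same seed => noise identical, so the difference is exactly the shift
  for (v in c("bio1", "bio12")) {
    expect_equal(s45$values[, v] - sb$values[, v],
                 rep(scenario_shift(rcp45)[v], nrow(cc)),
                 ignore_attr = TRUE)
  }
  # nested pathways: RCP8.5 shift magnitude >= RCP4.5, per variable
  expect_true(all(abs(scenario_shift(rcp85)) >= abs(scenario_shift(rcp45))))
  expect_error(domain_spec(lat_min = 0, lat_max = 0), "lat_max")
  expect_error(domain_spec(lat_min = -1.3, lat_max = 0, cell_size = 0.5),
               "multiple")
})

test_that("a fixed seed reproduces stacks bit-identically; seeds differ only in noise", {
  d <- domain_spec(lat_min = -5, lat_max = 0, lon_min = -55, lon_max = -50,
                   cell_size = 0.5)
  sc <- scenario_spec("g", "baseline")
  a <- generate_climate(d, sc, seed = 11)
  b <- generate_climate(d, sc, seed = 11)
  expect_identical(a$values, b$values)
  c2 <- generate_climate(d, sc, seed = 12)
  det <- generate_climate(d, sc, noise_sd = 0, seed = 1)$values
  expect_false(identical(a$values, c2$values))
  # deterministic parts agree; residuals are pure noise with the right scale
  res_a <- a$values - det
  res_c <- c2$values - det
  expect_false(identical(res_a, res_c))
  expect_lt(abs(stats::sd(res_a[, "bio1"]) - 0.15), 0.05)
})

test_that("landcover rules partition the domain and shift boundaries analytically", {
  w <- noiseless_world()
  expect_true(all(!is.na(w$landcover)))
  expect_length(w$landcover, w$domain$n_lat * w$domain$n_lon)

  # single always-true rule: uniform map
  uni <- rule_set(list(list(category = "A",
                            conditions = list(list(var = "bio1", op = ">",
                                                   value = -Inf)))))
  expect_true(all(generate_landcover(w$stack, uni) == "A"))

  # one threshold on a monotone gradient: a single latitudinal boundary
  rs <- rule_set(list(list(category = "forest",
                           conditions = list(list(var = "bio1", op = ">",
                                                  value = 24)))),
                 default_category = "shrub")
  lc <- generate_landcover(w$stack, rs)
  cc <- cell_centers(w$domain)
  boundary_lat <- (24 - 28) / 0.45  # bio1 = 28 + 0.45 * lat
  expect_true(all((lc == "forest") == (cc$lat > boundary_lat)))

  # under a warming shift the boundary moves south by shift/slope degrees
  d_temp <- 0.9
  fut <- generate_climate(w$domain,
                          scenario_spec("g", "RCP4.5", d_temp = d_temp,
                                        d_prec = 0),
                          noise_sd = 0, seed = 1)
  lc_f <- generate_landcover(fut, rs)
  expect_true(all((lc_f == "forest") == (cc$lat > boundary_lat - d_temp / 0.45)))

  # non-exhaustive rules fail, naming an uncovered cell
  partial <- rule_set(list(list(category = "forest",
                                conditions = list(list(var = "bio1", op = ">",
                                                       value = 24)))))
  expect_error(generate_landcover(w$stack, partial), "not exhaustive")
})

test_that("anthropogenic fractions follow hotspots, stay bounded and are reproducible", {
  d <- domain_spec(lat_min = -5, lat_max = 0, lon_min = -55, lon_max = -50,
                   cell_size = 0.5)
  lc <- rep("shrubland", d$n_lat * d$n_lon)
  expect_true(all(apply_anthropogenic(lc, d)$anthro_fraction == 0))
  whole <- list(list(lat = -2.5, lon = -52.5, radius = 90, intensity = 0.8))
  expect_true(all(apply_anthropogenic(lc, d, whole)$anthro_fraction == 0.8))
  j1 <- apply_anthropogenic(lc, d, whole, jitter_sd = 0.1, seed = 5)
  j2 <- apply_anthropogenic(lc, d, whole, jitter_sd = 0.1, seed = 5)
  expect_identical(j1, j2)
  expect_true(all(j1$anthro_fraction >= 0 & j1$anthro_fraction <= 1))
})

test_that("true future distributions obey identity and containment, with extirpation possible", {
  w <- noiseless_world(cell_size = 1)
  rules <- default_rules()
  same <- true_future_distribution(rules, w$stack, w$stack)
  expect_identical(same$refuge, same$current)

  fut <- generate_climate(w$domain,
                          scenario_spec("g", "RCP8.5", d_temp = 1, d_prec = -150),
                          noise_sd = 0, seed = 1)
  tf <- true_future_distribution(rules, w$stack, fut)
  expect_true(all(tf$refuge <= tf$current))
  expect_true(all(tf$refuge <= tf$future))

  # a shift large enough that no cell stays cool: sparse vegetation extirpated
  hot <- generate_climate(w$domain,
                          scenario_spec("g", "RCP8.5", d_temp = 10, d_prec = 0),
                          noise_sd = 0, seed = 1)
  tf2 <- true_future_distribution(rules, w$stack, hot)
  expect_equal(sum(tf2$future[, "sparse_vegetation"]), 0)
  expect_equal(sum(tf2$refuge[, "sparse_vegetation"]), 0)

  other <- generate_climate(domain_spec(cell_size = 0.5),
                            scenario_spec("g", "baseline"), 0, 1)
  expect_error(true_future_distribution(rules, w$stack, other),
               "different grids")
})
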