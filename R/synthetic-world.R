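# Synthetic gridded world: climate layers with known gradients, landcover
# generated from explicit climate rules, anthropogenic cover, and future
# scenarios built as additive shifts. Everything downstream is testable
# against these generating rules.

#' Define a regular lat/lon analysis grid
#'
#' The grid is cell-registered: cell edges fall on multiples of `cell_size`
#' and all coordinates reported by the package refer to cell centers.
#'
#' @param lat_min,lat_max,lon_min,lon_max Domain extent in decimal degrees.
#' @param cell_size Cell edge length in degrees (default 0.5).
#' @return An object of class `domain_spec` with the extent, cell size and
#'   derived grid dimensions `n_lat` (rows, north to south) and `n_lon`.
#' @export
domain_spec <- function(lat_min = -20, lat_max = 0, lon_min = -70,
                        lon_max = -50, cell_size = 0.5) {
  if (!(lat_max > lat_min) || !(lon_max > lon_min))
    stop("domain extent must satisfy lat_max > lat_min and lon_max > lon_min")
  if (cell_size <= 0) stop("cell_size must be positive")
  n_lat <- (lat_max - lat_min) / cell_size
  n_lon <- (lon_max - lon_min) / cell_size
  if (abs(n_lat - round(n_lat)) > 1e-8 || abs(n_lon - round(n_lon)) > 1e-8)
    stop("domain extent must be an integer multiple of cell_size")
  for (edge in c(lat_min, lat_max, lon_min, lon_max)) {
    if (abs(edge / cell_size - round(edge / cell_size)) > 1e-8)
      stop("grid edges must fall on multiples of cell_size")
  }
  n_lat <- as.integer(round(n_lat)); n_lon <- as.integer(round(n_lon))
  if (n_lat < 1L || n_lon < 1L) stop("grid dimensions must be positive")
  structure(list(lat_min = lat_min, lat_max = lat_max, lon_min = lon_min,
                 lon_max = lon_max, cell_size = cell_size,
                 n_lat = n_lat, n_lon = n_lon),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("domain_spec: %d x %d cells of %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$n_lat, x$n_lon, x$cell_size, x$lat_min, x$lat_max,
              x$lon_min, x$lon_max))
  invisible(x)
}

#' Cell centers of a grid
#'
#' Cells are numbered row-major from the north-west corner (row 1 is the
#' northernmost band), matching the north-up raster convention.
#'
#' @param domain A [domain_spec()].
#' @return Data frame with `cell_id`, `row`, `col`, `lat`, `lon` (centers).
#' @export
cell_centers <- function(domain) {
  stopifnot(inherits(domain, "domain_spec"))
  rows <- rep(seq_len(domain$n_lat), each = domain$n_lon)
  cols <- rep(seq_len(domain$n_lon), times = domain$n_lat)
  data.frame(
    cell_id = seq_len(domain$n_lat * domain$n_lon),
    row = rows, col = cols,
    lat = domain$lat_max - (rows - 0.5) * domain$cell_size,
    lon = domain$lon_min + (cols - 0.5) * domain$cell_size
  )
}

#' Define a climate scenario (pseudo-GCM x emission pathway)
#'
#' A scenario is an additive shift applied on top of the deterministic
#' climate gradients. The baseline (pre-industrial) scenario has zero shift;
#' RCP8.5 shifts are scaled to be at least as large in magnitude as RCP4.5,
#' per variable, emulating nested emission pathways.
#'
#' @param gcm_id Label of the pseudo climate model (e.g. "GCM-A").
#' @param rcp_id One of `"baseline"`, `"RCP4.5"`, `"RCP8.5"`.
#' @param d_temp Warming (deg C) added to every temperature-like variable at
#'   RCP4.5 scale.
#' @param d_prec Precipitation change (mm) added to every precipitation-like
#'   variable at RCP4.5 scale (typically negative: drying).
#' @param rcp85_scale Multiplier applied to the shifts under RCP8.5
#'   (default 2; must be >= 1 so pathways are nested).
#' @param horizon_year Nominal projection year (metadata only).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(gcm_id, rcp_id = c("baseline", "RCP4.5", "RCP8.5"),
                          d_temp = 1, d_prec = -150, rcp85_scale = 2,
                          horizon_year = 2080) {
  rcp_id <- match.arg(rcp_id)
  if (rcp85_scale < 1) stop("rcp85_scale must be >= 1 (nested pathways)")
  structure(list(gcm_id = gcm_id, rcp_id = rcp_id, d_temp = d_temp,
                 d_prec = d_prec, rcp85_scale = rcp85_scale,
                 horizon_year = horizon_year),
            class = "scenario_spec")
}

#' Bioclimatic variable metadata used by the generator
#'
#' Nineteen variables: bio1..bio11 are temperature-like (deg C, latitudinal
#' gradient), bio12..bio19 precipitation-like (mm, longitudinal gradient).
#' Each variable's deterministic surface is `base + slope * lat` (or
#' `* lon`), so the inter-cell climate step is `slope * cell_size`.
#'
#' @return Data frame with `variable`, `kind`, `unit`, `base`, `slope`.
#' @export
climate_variables <- function() {
  jt <- 1:11; jp <- 12:19
  data.frame(
    variable = paste0("bio", 1:19),
    kind = c(rep("temperature", 11), rep("precipitation", 8)),
    unit = c(rep("degC", 11), rep("mm", 8)),
    base = c(28 - 0.8 * (jt - 1), 8000 - 300 * (jp - 12)),
    slope = c(0.45 + 0.01 * (jt - 1), 100 - 5 * (jp - 12))
  )
}

#' Per-variable additive shift of a scenario
#'
#' @param scenario A [scenario_spec()].
#' @return Named numeric vector over bio1..bio19 (zero for baseline).
#' @export
scenario_shift <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  vars <- climate_variables()
  scale <- switch(scenario$rcp_id, baseline = 0, "RCP4.5" = 1,
                  "RCP8.5" = scenario$rcp85_scale)
  shift <- ifelse(vars$kind == "temperature",
                  scenario$d_temp, scenario$d_prec) * scale
  stats::setNames(shift, vars$variable)
}

# Deterministic (noise-free) climate value at arbitrary coordinates.
climate_deterministic <- function(lat, lon, scenario) {
  vars <- climate_variables()
  shift <- scenario_shift(scenario)
  out <- matrix(NA_real_, length(lat), nrow(vars),
                dimnames = list(NULL, vars$variable))
  for (j in seq_len(nrow(vars))) {
    coord <- if (vars$kind[j] == "temperature") lat else lon
    out[, j] <- vars$base[j] + vars$slope[j] * coord + shift[j]
  }
  out
}

#' Generate a 19-layer climate stack
#'
#' Each variable is a smooth deterministic gradient (latitudinal for
#' temperature-like variables, longitudinal for precipitation-like ones)
#' plus the scenario's additive shift plus independent Gaussian noise.
#' The noise field depends only on `(domain, seed)`, never on the scenario,
#' so two stacks generated with the same seed differ exactly by their
#' configured shifts.
#'
#' @param domain A [domain_spec()].
#' @param scenario A [scenario_spec()].
#' @param noise_sd Noise standard deviation: a single number, or a length-2
#'   vector `c(temperature, precipitation)`, or a named vector over
#'   bio1..bio19. Defaults to 0.15 deg C / 20 mm.
#' @param seed Integer seed (required; determinism is part of the contract).
#' @param smooth_noise If `TRUE`, the noise field of each variable is
#'   smoothed with a 3x3 spatial kernel, adding spatial autocorrelation.
#' @return Object of class `climate_stack`: list with `domain`, `scenario`,
#'   `values` (cells x 19 matrix, rows ordered as [cell_centers()]) and
#'   `units` metadata.
#' @export
generate_climate <- function(domain, scenario, noise_sd = c(0.15, 20),
                             seed = 1, smooth_noise = FALSE) {
  stopifnot(inherits(domain, "domain_spec"), inherits(scenario, "scenario_spec"))
  vars <- climate_variables()
  sd_vec <- expand_noise_sd(noise_sd, vars)
  if (any(sd_vec < 0)) stop("noise_sd must be non-negative")
  cc <- cell_centers(domain)
  values <- climate_deterministic(cc$lat, cc$lon, scenario)
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(values))) {
    eps <- stats::rnorm(nrow(cc), 0, 1)
    if (smooth_noise) eps <- smooth_field(eps, domain)
    values[, j] <- values[, j] + sd_vec[j] * eps
  }
  structure(list(domain = domain, scenario = scenario, values = values,
                 units = stats::setNames(vars$unit, vars$variable)),
            class = "climate_stack")
}

expand_noise_sd <- function(noise_sd, vars) {
  if (!is.null(names(noise_sd)) && all(vars$variable %in% names(noise_sd)))
    return(as.numeric(noise_sd[vars$variable]))
  if (length(noise_sd) == 1) return(rep(as.numeric(noise_sd), nrow(vars)))
  if (length(noise_sd) == 2)
    return(ifelse(vars$kind == "temperature", noise_sd[1], noise_sd[2]))
  stop("noise_sd must be length 1, length 2, or named over bio1..bio19")
}

# 3x3 mean smoothing of a cell-vector viewed as the grid matrix.
smooth_field <- function(eps, domain) {
  m <- matrix(eps, nrow = domain$n_lat, ncol = domain$n_lon, byrow = TRUE)
  padded <- m[c(1, seq_len(domain$n_lat), domain$n_lat),
              c(1, seq_len(domain$n_lon), domain$n_lon)]
  out <- m
  for (i in seq_len(domain$n_lat)) for (j in seq_len(domain$n_lon)) {
    out[i, j] <- mean(padded[i:(i + 2), j:(j + 2)])
  }
  as.vector(t(out))
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d cells x %d variables, gcm=%s rcp=%s\n",
              nrow(x$values), ncol(x$values), x$scenario$gcm_id,
              x$scenario$rcp_id))
  invisible(x)
}

#' Landcover category registry
#'
#' Five native categories generated by the synthetic rules plus two
#' anthropogenic ones used to exercise majority upscaling and removal.
#'
#' @return Data frame with `label`, `id` (ordinal used as deterministic
#'   tie-break in the majority vote) and `native` flag.
#' @export
default_categories <- function() {
  data.frame(
    label = c("closed_forest", "open_vegetation", "deciduous_forest",
              "shrubland", "sparse_vegetation", "urban", "agriculture"),
    id = 1:7,
    native = c(rep(TRUE, 5), FALSE, FALSE)
  )
}

#' Build an ordered climate-to-landcover rule set
#'
#' Rules are evaluated in order and the first match wins; `default_category`
#' catches the remainder, making the set exhaustive. Each rule is a
#' conjunction of single-variable threshold conditions.
#'
#' @param rules List of rules; each rule is
#'   `list(category =, conditions = list(list(var =, op =, value =), ...))`
#'   with `op` one of `">"`, `">="`, `"<"`, `"<="`.
#' @param default_category Category assigned when no rule matches, or `NULL`
#'   to require explicit coverage (uncovered cells then raise an error).
#' @return Object of class `rule_set`.
#' @export
rule_set <- function(rules, default_category = NULL) {
  for (r in rules) {
    if (is.null(r$category) || is.null(r$conditions))
      stop("each rule needs a category and a conditions list")
    for (cond in r$conditions) {
      if (!cond$op %in% c(">", ">=", "<", "<="))
        stop("unsupported rule operator: ", cond$op)
    }
  }
  structure(list(rules = rules, default_category = default_category),
            class = "rule_set")
}

#' Default generating rules of the synthetic world
#'
#' Nested thresholds on annual mean temperature (bio1) and annual
#' precipitation (bio12): warm/wet = closed forest, warm/dry = open
#' vegetation, mild/wet = deciduous forest, mild/dry = shrubland, cool =
#' sparse vegetation (default).
#'
#' @return A [rule_set()].
#' @export
default_rules <- function() {
  rule_set(list(
    list(category = "closed_forest",
         conditions = list(list(var = "bio1", op = ">", value = 25),
                           list(var = "bio12", op = ">", value = 2000))),
    list(category = "open_vegetation",
         conditions = list(list(var = "bio1", op = ">", value = 25))),
    list(category = "deciduous_forest",
         conditions = list(list(var = "bio1", op = ">", value = 22),
                           list(var = "bio12", op = ">", value = 1600))),
    list(category = "shrubland",
         conditions = list(list(var = "bio1", op = ">", value = 22)))
  ), default_category = "sparse_vegetation")
}

apply_rules_matrix <- function(values, rules) {
  n <- nrow(values)
  out <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (r in rules$rules) {
    match <- unassigned
    for (cond in r$conditions) {
      if (!cond$var %in% colnames(values))
        stop("rule references unknown variable: ", cond$var)
      x <- values[, cond$var]
      ok <- switch(cond$op, ">" = x > cond$value, ">=" = x >= cond$value,
                   "<" = x < cond$value, "<=" = x <= cond$value)
      match <- match & ok
    }
    out[match] <- r$category
    unassigned <- unassigned & !match
  }
  if (any(unassigned)) {
    if (is.null(rules$default_category))
      stop("rule set is not exhaustive: first uncovered cell is ",
           which(unassigned)[1])
    out[unassigned] <- rules$default_category
  }
  out
}

#' Generate landcover from climate via the rule set
#'
#' @param climate A `climate_stack`.
#' @param rules A [rule_set()].
#' @param subdivide Integer k; if > 1, also returns a fine-resolution label
#'   matrix obtained by evaluating the rules on the deterministic climate at
#'   k x k sub-cell centers (used to exercise majority upscaling).
#' @return Character vector of labels over cells; if `subdivide > 1` the
#'   fine matrix is attached as attribute `"fine"` ((n_lat*k) x (n_lon*k),
#'   north-up).
#' @export
generate_landcover <- function(climate, rules, subdivide = 1) {
  stopifnot(inherits(climate, "climate_stack"), inherits(rules, "rule_set"))
  labels <- apply_rules_matrix(climate$values, rules)
  if (subdivide > 1) {
    k <- as.integer(subdivide)
    d <- climate$domain
    fine_dom <- domain_spec(d$lat_min, d$lat_max, d$lon_min, d$lon_max,
                            d$cell_size / k)
    fc <- cell_centers(fine_dom)
    fine_vals <- climate_deterministic(fc$lat, fc$lon, climate$scenario)
    fine_labels <- apply_rules_matrix(fine_vals, rules)
    attr(labels, "fine") <- matrix(fine_labels, nrow = fine_dom$n_lat,
                                   ncol = fine_dom$n_lon, byrow = TRUE)
  }
  labels
}

#' Overlay anthropogenic cover hotspots on a landcover map
#'
#' Each hotspot is a disc (`lat`, `lon`, `radius` in degrees, `intensity`
#' in \[0,1\]); a cell's anthropogenic fraction is the maximum intensity of
#' the hotspots covering its center, optionally jittered with Gaussian
#' noise and clamped to \[0,1\]. The native label is preserved alongside.
#'
#' @param landcover Character labels over cells (from [generate_landcover()]).
#' @param domain The grid.
#' @param hotspots List of `list(lat=, lon=, radius=, intensity=)`; empty
#'   list gives fraction 0 everywhere.
#' @param jitter_sd Standard deviation of the optional noise (default 0).
#' @param seed Seed for the jitter.
#' @return A cell table: [cell_centers()] columns plus `landcover`,
#'   `anthro_fraction`, `area_km2`.
#' @export
apply_anthropogenic <- function(landcover, domain, hotspots = list(),
                                jitter_sd = 0, seed = 1) {
  cc <- cell_centers(domain)
  if (length(landcover) != nrow(cc))
    stop("landcover length does not match the grid")
  frac <- rep(0, nrow(cc))
  for (h in hotspots) {
    d <- sqrt((cc$lat - h$lat)^2 + (cc$lon - h$lon)^2)
    inside <- d <= h$radius
    frac[inside] <- pmax(frac[inside], h$intensity)
  }
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    frac <- frac + stats::rnorm(nrow(cc), 0, jitter_sd)
  }
  frac <- pmin(pmax(frac, 0), 1)
  cells <- cc
  cells$landcover <- as.character(landcover)
  cells$anthro_fraction <- frac
  cells$area_km2 <- cell_area_km2(cells$lat, domain$cell_size)
  cells
}

#' Ground-truth current/future distributions and refuges
#'
#' Applies the generating rules to a baseline and a future climate stack and
#' intersects the per-category maps: a true refuge cell keeps the same
#' category under both climates.
#'
#' @param rules The generating [rule_set()] (must be the one used at baseline).
#' @param baseline,future `climate_stack`s on the same grid.
#' @return List of logical cells-x-category matrices `current`, `future`,
#'   `refuge` (refuge = current AND future, per category).
#' @export
true_future_distribution <- function(rules, baseline, future) {
  if (!identical(unclass(baseline$domain), unclass(future$domain)))
    stop("baseline and future stacks are on different grids")
  cur <- apply_rules_matrix(baseline$values, rules)
  fut <- apply_rules_matrix(future$values, rules)
  cats <- sort(unique(c(cur, fut)))
  mk <- function(lab) vapply(cats, function(k) lab == k,
                             logical(length(lab)))
  current <- mk(cur); future_m <- mk(fut)
  list(current = current, future = future_m,
       refuge = current & future_m)
}

#' Default pseudo-GCM ensemble
#'
#' Three pseudo climate models that disagree in shift magnitude and
#' direction, emulating inter-model uncertainty: GCM-A (+1.0 degC, -150 mm),
#' GCM-B (+1.2 degC, -100 mm), GCM-C (+0.8 degC, -200 mm) at RCP4.5 scale;
#' RCP8.5 doubles the shifts.
#'
#' @return Named list of per-GCM parameter lists (`d_temp`, `d_prec`).
#' @export
default_gcms <- function() {
  list("GCM-A" = list(d_temp = 1.0, d_prec = -150),
       "GCM-B" = list(d_temp = 1.2, d_prec = -100),
       "GCM-C" = list(d_temp = 0.8, d_prec = -200))
}
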