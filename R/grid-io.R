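# Grid geometry and plain-text I/O: ESRI ASCII grids for rasters, CSV cell
# tables, GeoJSON region polygons, majority upscaling and anthropogenic
# filtering.

EARTH_RADIUS_KM <- 6371

#' Area of a lat/lon grid cell
#'
#' Spherical band formula, `A = R^2 * d_lambda * (sin(phi_top) -
#' sin(phi_bottom))` with R = 6371 km. Exact on the sphere; cell areas
#' shrink with latitude.
#'
#' @param lat_center Latitude(s) of cell centers, degrees.
#' @param cell_size Cell edge, degrees.
#' @return Area(s) in km^2.
#' @export
cell_area_km2 <- function(lat_center, cell_size) {
  if (any(abs(lat_center) + cell_size / 2 > 90 + 1e-12))
    stop("cell extends beyond a pole: |lat_center| + cell_size/2 > 90")
  rad <- pi / 180
  top <- (lat_center + cell_size / 2) * rad
  bot <- (lat_center - cell_size / 2) * rad
  EARTH_RADIUS_KM^2 * (cell_size * rad) * (sin(top) - sin(bot))
}

#' Upscale a fine landcover map by native-majority vote
#'
#' Each analysis cell receives the most abundant *native* category among its
#' fine pixels; anthropogenic pixels are excluded from the vote but counted
#' into `anthro_fraction`. Ties break toward the smaller category ordinal in
#' the registry. Cells with no native pixel at all are dropped (reported via
#' a message).
#'
#' @param fine_map Character matrix (north-up) of fine labels; its dimensions
#'   must be an integer multiple of the analysis grid's.
#' @param domain Target [domain_spec()].
#' @param registry Category registry (see [default_categories()]).
#' @return Cell table: `cell_id`, `row`, `col`, `lat`, `lon`, `landcover`
#'   (native modal label), `anthro_fraction`, `area_km2`.
#' @export
upscale_majority <- function(fine_map, domain, registry = default_categories()) {
  stopifnot(inherits(domain, "domain_spec"))
  k_lat <- nrow(fine_map) / domain$n_lat
  k_lon <- ncol(fine_map) / domain$n_lon
  if (abs(k_lat - round(k_lat)) > 1e-9 || abs(k_lon - round(k_lon)) > 1e-9)
    stop(sprintf(
      "fine map (%d x %d) is misaligned with the %d x %d analysis grid",
      nrow(fine_map), ncol(fine_map), domain$n_lat, domain$n_lon))
  k_lat <- as.integer(round(k_lat)); k_lon <- as.integer(round(k_lon))
  unknown <- setdiff(unique(as.vector(fine_map)), registry$label)
  if (length(unknown))
    stop("unknown landcover label(s): ", paste(unknown, collapse = ", "))
  native_set <- registry$label[registry$native]
  ordinal <- stats::setNames(registry$id, registry$label)

  cc <- cell_centers(domain)
  out_label <- rep(NA_character_, nrow(cc))
  out_frac <- rep(NA_real_, nrow(cc))
  for (i in seq_len(nrow(cc))) {
    ri <- (cc$row[i] - 1) * k_lat + seq_len(k_lat)
    ci <- (cc$col[i] - 1) * k_lon + seq_len(k_lon)
    px <- as.vector(fine_map[ri, ci])
    is_native <- px %in% native_set
    out_frac[i] <- mean(!is_native)
    if (any(is_native)) {
      tab <- table(px[is_native])
      best <- names(tab)[tab == max(tab)]
      out_label[i] <- best[which.min(ordinal[best])]
    }
  }
  keep <- !is.na(out_label)
  if (any(!keep))
    message(sum(!keep), " cell(s) without native pixels dropped from the grid")
  cells <- cc[keep, , drop = FALSE]
  cells$landcover <- out_label[keep]
  cells$anthro_fraction <- out_frac[keep]
  cells$area_km2 <- cell_area_km2(cells$lat, domain$cell_size)
  rownames(cells) <- NULL
  cells
}

#' Remove cells whose landcover is an anthropogenic category
#'
#' `anthro_fraction` is retained on the remaining rows so the sensitivity
#' analysis stays possible.
#'
#' @param cells Cell table with a `landcover` column.
#' @param registry Category registry with `native` flags.
#' @return Filtered cell table; warns if the result is empty.
#' @export
drop_anthropogenic_categories <- function(cells, registry = default_categories()) {
  unknown <- setdiff(unique(cells$landcover), registry$label)
  if (length(unknown))
    stop("unknown landcover label(s): ", paste(unknown, collapse = ", "))
  native_set <- registry$label[registry$native]
  out <- cells[cells$landcover %in% native_set, , drop = FALSE]
  if (nrow(out) == 0)
    warning("all cells were anthropogenic; returning an empty cell table")
  rownames(out) <- NULL
  out
}

#' Write / read a single-band raster as an ESRI ASCII grid
#'
#' Plain-text, cell-registered, north-up; the value vector is ordered as
#' [cell_centers()] (row-major from the north-west corner). Round-trips are
#' lossless to the printed precision (15 significant digits).
#'
#' @param values Numeric vector over cells, or an `n_lat x n_lon` matrix.
#' @param domain The grid.
#' @param file Path of the `.asc` file.
#' @param na_value Sentinel written for `NA` cells (default -9999).
#' @return `file`, invisibly.
#' @export
write_raster <- function(values, domain, file, na_value = -9999) {
  stopifnot(inherits(domain, "domain_spec"))
  if (is.matrix(values)) {
    stopifnot(nrow(values) == domain$n_lat, ncol(values) == domain$n_lon)
    m <- values
  } else {
    stopifnot(length(values) == domain$n_lat * domain$n_lon)
    m <- matrix(values, nrow = domain$n_lat, ncol = domain$n_lon, byrow = TRUE)
  }
  header <- c(
    sprintf("ncols %d", domain$n_lon),
    sprintf("nrows %d", domain$n_lat),
    sprintf("xllcorner %.10f", domain$lon_min),
    sprintf("yllcorner %.10f", domain$lat_min),
    sprintf("cellsize %.10f", domain$cell_size),
    sprintf("NODATA_value %g", na_value)
  )
  body <- apply(m, 1, function(r) {
    r[is.na(r)] <- na_value
    paste(formatC(r, format = "g", digits = 15), collapse = " ")
  })
  writeLines(c(header, body), file)
  invisible(file)
}

#' @rdname write_raster
#' @param na_ok If `FALSE` (default), NODATA cells inside the grid are
#'   rejected with the offending cell ids listed.
#' @return For `read_raster`: list with `values` (vector over cells),
#'   `domain`, and `matrix` (north-up).
#' @export
read_raster <- function(file, na_ok = FALSE) {
  lines <- readLines(file)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  n_lat <- as.integer(hdr$nrows); n_lon <- as.integer(hdr$ncols)
  dom <- domain_spec(hdr$yllcorner, hdr$yllcorner + n_lat * hdr$cellsize,
                     hdr$xllcorner, hdr$xllcorner + n_lon * hdr$cellsize,
                     hdr$cellsize)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != n_lat * n_lon)
    stop(sprintf("raster body has %d values, expected %d (shape mismatch)",
                 length(vals), n_lat * n_lon))
  vals[vals == hdr$nodata_value] <- NA
  if (!na_ok && anyNA(vals)) {
    bad <- which(is.na(vals))
    stop("raster has missing data inside the domain at cell(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  list(values = vals, domain = dom,
       matrix = matrix(vals, nrow = n_lat, ncol = n_lon, byrow = TRUE))
}

#' Write / read a cell table as CSV
#'
#' Rows are stored and returned in canonical `cell_id` order, so shuffled
#' files round-trip to the identical table.
#'
#' @param cells Cell table (data frame with a `cell_id` column).
#' @param file CSV path.
#' @export
write_cells <- function(cells, file) {
  stopifnot("cell_id" %in% names(cells))
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  utils::write.csv(cells, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cells
#' @export
read_cells <- function(file) {
  cells <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cells)) stop("cell table lacks a cell_id column")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id values in ", file)
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Write / read region polygons as GeoJSON
#'
#' Supports a FeatureCollection of simple polygons (outer ring only, WGS84
#' lon/lat), which is all the refugia reporting needs.
#'
#' @param regions Named list of polygons; each polygon is a two-column
#'   matrix of (lon, lat) vertices (closed or open ring).
#' @param file GeoJSON path.
#' @export
write_regions <- function(regions, file) {
  features <- lapply(names(regions), function(nm) {
    ring <- regions[[nm]]
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_regions
#' @return For `read_regions`: named list of (lon, lat) vertex matrices.
#' @export
read_regions <- function(file) {
  gj <- jsonlite::read_json(file)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon geometries are supported, got ", f$geometry$type)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("region_", length(out) + 1)
    out[[nm]] <- ring
  }
  out
}

#' Rectangular tiling of the domain into synthetic regions
#'
#' Splits the domain into an `ny x nx` grid of rectangles (named R1, R2, ...)
#' that exactly partition it; stands in for country polygons in synthetic
#' runs and is labelled synthetic accordingly.
#'
#' @param domain The grid.
#' @param nx,ny Number of tiles along longitude / latitude.
#' @return Named list of (lon, lat) vertex matrices.
#' @export
synthetic_regions <- function(domain, nx = 2, ny = 2) {
  lon_edges <- seq(domain$lon_min, domain$lon_max, length.out = nx + 1)
  lat_edges <- seq(domain$lat_min, domain$lat_max, length.out = ny + 1)
  out <- list()
  k <- 1
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    out[[paste0("R", k)]] <- cbind(
      lon = c(lon_edges[j], lon_edges[j + 1], lon_edges[j + 1], lon_edges[j]),
      lat = c(lat_edges[i], lat_edges[i], lat_edges[i + 1], lat_edges[i + 1]))
    k <- k + 1
  }
  out
}
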