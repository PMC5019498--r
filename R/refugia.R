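# Refugia: stability maps (current AND future), range areas, area-weighted
# centroids, great-circle displacement, and per-region refuge accounting.

#' Stability (refuge) map of one category
#'
#' A refuge cell keeps the category under both current climate and the
#' cross-GCM future consensus: cellwise AND.
#'
#' @param current_binary,future_binary Logical vectors over the same cells.
#' @return Logical refuge vector.
#' @export
stability_map <- function(current_binary, future_binary) {
  if (length(current_binary) != length(future_binary))
    stop("current and future maps are on different grids")
  as.logical(current_binary) & as.logical(future_binary)
}

#' Range area in km^2 and as a share of the domain
#'
#' @param binary Logical presence vector.
#' @param cell_areas Cell areas in km^2.
#' @return List `km2`, `pct` (percent of the summed modeled-domain area).
#' @export
range_area <- function(binary, cell_areas) {
  stopifnot(length(binary) == length(cell_areas))
  km2 <- sum(cell_areas[as.logical(binary)])
  list(km2 = km2, pct = 100 * km2 / sum(cell_areas))
}

#' Area-weighted range centroid
#'
#' Latitude and longitude of present cells averaged with cell-area weights
#' (the domain is assumed far from the antimeridian). An empty range is an
#' extirpation, reported as such rather than as a number.
#'
#' @param binary Logical presence vector.
#' @param lat,lon Cell center coordinates.
#' @param cell_areas Cell areas in km^2.
#' @return List `extirpated` (logical), `lat`, `lon` (`NA` when extirpated).
#' @export
range_centroid <- function(binary, lat, lon, cell_areas) {
  binary <- as.logical(binary)
  if (!any(binary))
    return(list(extirpated = TRUE, lat = NA_real_, lon = NA_real_))
  w <- cell_areas[binary]
  list(extirpated = FALSE,
       lat = sum(lat[binary] * w) / sum(w),
       lon = sum(lon[binary] * w) / sum(w))
}

#' Great-circle displacement between two centroids
#'
#' Haversine distance (Earth radius 6371 km) and initial bearing from the
#' current to the future centroid. Undefined if either range is extirpated.
#'
#' @param centroid_current,centroid_future Outputs of [range_centroid()].
#' @return List `defined`, `km`, `bearing_deg` (initial bearing, 0-360).
#' @export
displacement <- function(centroid_current, centroid_future) {
  if (isTRUE(centroid_current$extirpated) || isTRUE(centroid_future$extirpated))
    return(list(defined = FALSE, km = NA_real_, bearing_deg = NA_real_))
  p1 <- c(centroid_current$lon, centroid_current$lat)
  p2 <- c(centroid_future$lon, centroid_future$lat)
  km <- geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
  b <- geosphere::bearing(p1, p2) %% 360
  list(defined = TRUE, km = km, bearing_deg = b)
}

#' Refuge areas by region polygon
#'
#' Cells are assigned to the region polygon containing their center;
#' overlapping polygons are an error (listing the overlaps), gaps are
#' allowed and reported via a message.
#'
#' @param refuge_binaries Logical cells x categories matrix (or a single
#'   logical vector).
#' @param regions Named list of (lon, lat) polygon vertex matrices
#'   (see [read_regions()]).
#' @param lat,lon Cell centers.
#' @param cell_areas Cell areas, km^2.
#' @return Data frame: `region`, `category`, `km2`, `pct_of_region`.
#' @export
refuges_by_region <- function(refuge_binaries, regions, lat, lon,
                              cell_areas) {
  if (is.null(dim(refuge_binaries)))
    refuge_binaries <- matrix(refuge_binaries, ncol = 1,
                              dimnames = list(NULL, "all"))
  pts <- cbind(lon, lat)
  membership <- vapply(regions, function(poly)
    mgcv::in.out(rbind(poly, poly[1, ]), pts), logical(nrow(pts)))
  multi <- rowSums(membership) > 1
  if (any(multi)) {
    pairs <- unique(apply(membership[multi, , drop = FALSE], 1, function(r)
      paste(names(regions)[r], collapse = " & ")))
    stop("overlapping region polygons: ", paste(pairs, collapse = "; "))
  }
  if (any(rowSums(membership) == 0))
    message(sum(rowSums(membership) == 0),
            " cell center(s) fall outside every region (gap)")
  rows <- list()
  for (rg in names(regions)) {
    inr <- membership[, rg]
    region_area <- sum(cell_areas[inr])
    for (k in colnames(refuge_binaries)) {
      km2 <- sum(cell_areas[inr & refuge_binaries[, k]])
      rows[[length(rows) + 1]] <- data.frame(
        region = rg, category = k, km2 = km2,
        pct_of_region = if (region_area > 0) 100 * km2 / region_area else 0)
    }
  }
  do.call(rbind, rows)
}

#' Jaccard similarity of two binary maps
#'
#' Intersection over union; two empty maps are identical (Jaccard 1).
#'
#' @param a,b Logical vectors over the same cells.
#' @return Value in \[0,1\].
#' @export
jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
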