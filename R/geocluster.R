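#' Great-circle distance in miles
#'
#' Haversine distance on a sphere of radius 3958.8 miles.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance(s) in miles.
#' @examples
#' haversine_miles(0, 0, 1, 0) # one degree of latitude
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 3958.8)
}

check_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon)) stop("coordinates must not contain NA")
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  invisible(TRUE)
}

#' Group locations into clusters of bounded spatial extent
#'
#' Complete-linkage agglomerative clustering on pairwise great-circle
#' distances, cut so that no cluster's maximum pairwise distance (diameter)
#' exceeds `max_diameter`. Complete linkage is used because its merge height
#' is exactly the merged cluster's diameter, so cutting the tree at
#' `max_diameter` enforces the bound directly. Locations are processed in
#' `location_id` order and clusters are labelled by their smallest member id,
#' making the partition invariant to input order.
#'
#' The resulting cluster ids are the grouping level for cluster-robust
#' standard errors downstream.
#'
#' @param points a data frame with columns `location_id`, `lat`, `lon`.
#' @param max_diameter maximum allowed intra-cluster pairwise distance, miles
#'   (default 50).
#' @return a data frame `location_id`, `cluster_id` with attribute
#'   `"diameters"`: a named numeric vector of recomputed per-cluster maximum
#'   pairwise distances (miles).
#' @export
cluster_max_diameter <- function(points, max_diameter = 50) {
  assert_columns(points, c("location_id", "lat", "lon"), "points")
  if (nrow(points) < 1L) stop("need at least one point")
  if (anyDuplicated(points$location_id)) stop("duplicate location ids")
  points <- points[order(points$location_id), , drop = FALSE]
  n <- nrow(points)
  if (n == 1L) {
    out <- data.frame(location_id = points$location_id, cluster_id = 1L,
                      stringsAsFactors = FALSE)
    attr(out, "diameters") <- c(`1` = 0)
    return(out)
  }
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dm[i, j] <- dm[j, i] <- haversine_miles(points$lat[i], points$lon[i],
                                            points$lat[j], points$lon[j])
  }
  hc <- hclust(as.dist(dm), method = "complete")
  member <- cutree(hc, h = max_diameter)
  # relabel clusters 1..K in order of their smallest location_id
  first <- tapply(seq_len(n), member, min)
  relabel <- rank(first)
  cluster_id <- as.integer(relabel[as.character(member)])
  diam <- vapply(split(seq_len(n), cluster_id), function(ix) {
    if (length(ix) == 1L) 0 else max(dm[ix, ix])
  }, numeric(1))
  if (any(diam > max_diameter + 1e-9)) {
    stop("internal error: cluster diameter bound violated") # audited invariant
  }
  out <- data.frame(location_id = points$location_id, cluster_id = cluster_id,
                    stringsAsFactors = FALSE)
  attr(out, "diameters") <- diam
  out
}
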