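# Spatially matched control sampling.  Crashes involving vehicles with at
# least one warning system (cases) are rare (< 3% of fatal crashes), so
# control crashes (no warning system) are sampled from the spatial
# neighbourhood of each case to hold location-driven heterogeneity fixed.

# Great-circle Earth radius in feet used throughout the package.
EARTH_RADIUS_FT <- 20902231

#' Great-circle (haversine) distance in feet
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.  Vectorized.
#' @return Distance(s) in feet along the great circle, with Earth radius
#'   fixed at 20,902,231 ft.
#' @export
haversine_ft <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90, abs(lat2) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(abs(lon1) > 180, abs(lon2) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_FT * asin(pmin(1, sqrt(a)))
}

#' k-nearest-neighbour control matching
#'
#' For each case crash, finds the `k` control-pool crashes with the smallest
#' great-circle distance.  The search is exact; ties are broken by pool
#' identifier order, so matching is deterministic.
#'
#' @param cases Data.frame of case records (outcome >= 1) with `crash_id`,
#'   `latitude`, `longitude`.
#' @param pool Data.frame of candidate controls (outcome = 0), same columns.
#' @param k Number of neighbours per case (default 3).
#' @return A `match_result` data.frame with one row per (case, rank):
#'   `case_id`, `rank`, `control_id`, `distance_ft`; distances are
#'   nondecreasing in rank within a case.
#' @export
knn_controls <- function(cases, pool, k = 3) {
  if (nrow(pool) < k) stop("control pool smaller than k = ", k)
  if (anyNA(cases$latitude) || anyNA(cases$longitude) ||
      anyNA(pool$latitude) || anyNA(pool$longitude))
    stop("coordinates must be complete for matching")
  ord_pool <- order(pool$crash_id)
  pool <- pool[ord_pool, , drop = FALSE]
  res <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    d <- haversine_ft(cases$latitude[i], cases$longitude[i],
                      pool$latitude, pool$longitude)
    # order() is stable, so equal distances resolve by identifier order
    sel <- order(d)[seq_len(k)]
    res[[i]] <- data.frame(case_id = cases$crash_id[i], rank = seq_len(k),
                           control_id = pool$crash_id[sel],
                           distance_ft = d[sel], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("match_result", "data.frame")
  out
}

#' Maximum k-th neighbour distance
#'
#' The largest distance, across cases, of the rank-`k` matched control; the
#' summary used to judge whether `k` neighbours stay spatially local.
#'
#' @param matches A `match_result` from [knn_controls()].
#' @param k Neighbour rank to inspect.
#' @return Distance in feet.
#' @export
max_kth_distance <- function(matches, k) {
  if (nrow(matches) == 0L) stop("no matches")
  if (!k %in% matches$rank) stop("rank k = ", k, " not present in matches")
  max(matches$distance_ft[matches$rank == k])
}

#' Profile of maximum k-th neighbour distance against k
#'
#' Supports choosing the neighbour count: as `k` grows the sample gains
#' controls but the worst-case matching distance grows, diluting spatial
#' proximity.  The choice of `k` is left to the analyst.
#'
#' @inheritParams knn_controls
#' @param k_max Largest neighbour count to profile.
#' @return Data.frame with columns `k` and `max_kth_distance_ft`
#'   (nondecreasing in `k`).
#' @export
knn_profile <- function(cases, pool, k_max = 10) {
  matches <- knn_controls(cases, pool, k = min(k_max, nrow(pool)))
  ks <- seq_len(min(k_max, nrow(pool)))
  data.frame(k = ks,
             max_kth_distance_ft = vapply(ks, function(kk)
               max_kth_distance(matches, kk), numeric(1)))
}

#' Assemble the matched analysis sample
#'
#' Unions all cases with their selected controls.  A control selected by
#' several cases enters the sample once.
#'
#' @param cases Case records.
#' @param pool Control-pool records the matches refer to.
#' @param matches A `match_result` from [knn_controls()].
#' @return A data.frame of cases plus deduplicated selected controls, with a
#'   `matched_role` column (`"case"`/`"control"`).
#' @export
build_matched_sample <- function(cases, pool, matches) {
  sel_ids <- unique(matches$control_id)
  controls <- pool[match(sel_ids, pool$crash_id), , drop = FALSE]
  cases$matched_role <- "case"
  controls$matched_role <- "control"
  out <- rbind(cases, controls)
  rownames(out) <- NULL
  out
}
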