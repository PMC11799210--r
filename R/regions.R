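#' Spatial clustering of occurrence paleocoordinates into regions
#'
#' Pools occurrences into unique spatial coordinates and partitions them by
#' agglomerative hierarchical clustering of the Euclidean distance matrix
#' of (lon, lat) in degrees. The partition is deterministic: points are
#' sorted lexicographically before clustering so that input row order is
#' irrelevant.
#'
#' @param points Tibble/data frame with columns `lon`, `lat` (paleo
#'   coordinates, decimal degrees); duplicates are collapsed.
#' @param k Number of clusters (default 10).
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   default "ward.D2".
#' @param great_circle If `TRUE`, use great-circle (haversine) distances in
#'   km instead of raw-degree Euclidean distances.
#' @return Tibble of unique points with columns `lon`, `lat`, `region_id`
#'   (integer 1..k, relabelled so region 1 holds the lexicographically
#'   first point).
#' @export
cluster_spatial <- function(points, k = 10L, linkage = "ward.D2",
                            great_circle = FALSE) {
  stopifnot(all(c("lon", "lat") %in% names(points)), k >= 2)
  pts <- tibble::as_tibble(points[, c("lon", "lat")]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$lon, .data$lat)
  if (nrow(pts) < k) {
    stop("fewer distinct points (", nrow(pts), ") than clusters k = ", k,
         call. = FALSE)
  }
  d <- if (great_circle) {
    as.dist(geosphere::distm(as.matrix(pts),
                             fun = geosphere::distHaversine) / 1000)
  } else {
    dist(as.matrix(pts))
  }
  grp <- cutree(hclust(d, method = linkage), k = k)
  # stable labels: number clusters by first appearance in sorted point order
  relabel <- match(grp, unique(grp))
  dplyr::mutate(pts, region_id = as.integer(relabel))
}

#' Ecological clustering of localities by species composition
#'
#' Partitions localities by agglomerative clustering of Jaccard distances
#' between their species presence/absence profiles. Clusters holding fewer
#' than `min_species` distinct species are removed (small samples tend to
#' drive dissimilarity through absences); their localities are returned
#' with `region_id = NA`.
#'
#' @param presence_matrix Logical/0-1 matrix, species in rows, localities
#'   in columns (column names identify localities).
#' @param k Number of clusters to cut (before the species filter).
#' @param min_species Minimum distinct species per retained cluster;
#'   default 14.
#' @param linkage Agglomeration method; default "average".
#' @return Tibble: `locality`, `region_id` (NA for filtered-out clusters),
#'   `n_species_cluster`.
#' @export
cluster_ecological <- function(presence_matrix, k = 10L, min_species = 14L,
                               linkage = "average") {
  m <- as.matrix(presence_matrix) > 0
  stopifnot(nrow(m) > 0, ncol(m) >= 2)
  k <- min(k, ncol(m))
  locs <- colnames(m) %||% as.character(seq_len(ncol(m)))
  d <- vegan::vegdist(t(m) * 1, method = "jaccard", binary = TRUE)
  grp <- cutree(hclust(d, method = linkage), k = k)
  n_sp <- vapply(seq_len(k), function(g) {
    sum(rowSums(m[, grp == g, drop = FALSE]) > 0)
  }, integer(1))
  keep <- n_sp >= min_species
  out <- tibble::tibble(
    locality = locs,
    region_id = ifelse(keep[grp], as.integer(grp), NA_integer_),
    n_species_cluster = n_sp[grp]
  )
  # renumber surviving clusters compactly by first appearance
  surv <- out$region_id[!is.na(out$region_id)]
  out$region_id[!is.na(out$region_id)] <- match(surv, unique(surv))
  out
}

#' Pair-counting agreement between two partitions
#'
#' Rand-type index: over all unordered pairs of shared items, the fraction
#' on which the two partitions agree (both co-assign or both separate).
#' Equals 1 iff the partitions are identical up to relabelling; symmetric.
#'
#' @param spatial,ecological Named vectors (or two-column data frames with
#'   `locality`, `region_id`) assigning a cluster label to each locality;
#'   only shared, non-NA localities are compared.
#' @return A one-row tibble: `k_spatial`, `k_ecological`, `n_items`,
#'   `agreement` in `[0, 1]`.
#' @export
partition_agreement <- function(spatial, ecological) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$region_id, x$locality) else x
  }
  a <- as_named(spatial); b <- as_named(ecological)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 2) {
    stop("need at least 2 shared classified localities", call. = FALSE)
  }
  a <- a[shared]; b <- b[shared]
  pairs <- utils::combn(length(shared), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  tibble::tibble(
    k_spatial = length(unique(a)),
    k_ecological = length(unique(b)),
    n_items = length(shared),
    agreement = mean(same_a == same_b)
  )
}

#' Scan cluster counts for spatial/ecological agreement
#'
#' Convenience wrapper: clusters the same localities spatially and
#' ecologically over a range of k and reports the pair-counting agreement
#' for each, to expose which spatial cluster count best matches the
#' faunal structure.
#'
#' @param points Locality coordinates (`locality`, `lon`, `lat`).
#' @param presence_matrix Species x locality incidence matrix with column
#'   names matching `points$locality`.
#' @param k_range Integer vector of cluster counts to try.
#' @param min_species Filter passed to [cluster_ecological()].
#' @return Tibble: `k`, `agreement`.
#' @export
agreement_scan <- function(points, presence_matrix, k_range = 2:12,
                           min_species = 14L) {
  purrr::map_dfr(k_range, function(k) {
    sp <- cluster_spatial(points[, c("lon", "lat")], k = k)
    sp_lab <- setNames(
      sp$region_id[match(paste(points$lon, points$lat),
                         paste(sp$lon, sp$lat))],
      points$locality)
    ec <- cluster_ecological(presence_matrix, k = k,
                             min_species = min_species)
    ag <- partition_agreement(sp_lab, ec)
    tibble::tibble(k = k, agreement = ag$agreement)
  })
}

#' Assign occurrences to regions and flag analyzable regions
#'
#' Maps each occurrence to the region of its (pooled) paleocoordinate and
#' computes per-region, per-bin occurrence counts. A region is flagged
#' analyzable when it has more than `min_occ_per_bin` occurrences in at
#' least two consecutive time bins, or when it appears in `whitelist`
#' (ecological grounds can justify retaining a region whose gaps are real
#' absences rather than sampling failures).
#'
#' @param occurrences Tibble with `occurrence_id`, `time_bin`, and the
#'   coordinate columns named by `coords`.
#' @param regions Output of [cluster_spatial()].
#' @param tb A [time_bins()] object.
#' @param min_occ_per_bin Strict lower bound on per-bin occurrences;
#'   default 25 (a bin counts only when occurrences > 25).
#' @param whitelist Integer vector of region ids to force-flag analyzable.
#' @param coords Length-2 character naming the lon/lat columns; default
#'   primary paleocoordinates.
#' @return A list: `assignment` (occurrence_id -> region_id tibble) and
#'   `regions` (tibble: region_id, n_occurrences, n_bins_over_threshold,
#'   analyzable, plus one count column per analysed bin).
#' @export
assign_regions <- function(occurrences, regions, tb = time_bins(),
                           min_occ_per_bin = 25L, whitelist = integer(),
                           coords = c("paleo_lon_primary",
                                      "paleo_lat_primary")) {
  stopifnot(all(c("occurrence_id", "time_bin", coords) %in%
                  names(occurrences)))
  key_occ <- paste(occurrences[[coords[1]]], occurrences[[coords[2]]])
  key_reg <- paste(regions$lon, regions$lat)
  region_id <- regions$region_id[match(key_occ, key_reg)]
  if (anyNA(region_id)) {
    # occurrences at coordinates unseen by the clustering: nearest point
    miss <- which(is.na(region_id))
    for (m in miss) {
      d <- (regions$lon - occurrences[[coords[1]]][m])^2 +
        (regions$lat - occurrences[[coords[2]]][m])^2
      region_id[m] <- regions$region_id[which.min(d)]
    }
  }
  assignment <- tibble::tibble(
    occurrence_id = occurrences$occurrence_id,
    region_id = as.integer(region_id)
  )
  counts <- tibble::tibble(region_id = assignment$region_id,
                           time_bin = occurrences$time_bin) |>
    dplyr::filter(.data$time_bin %in% tb$bins) |>
    dplyr::count(.data$region_id, .data$time_bin) |>
    tidyr::pivot_wider(names_from = "time_bin", values_from = "n",
                       values_fill = 0L)
  for (b in setdiff(tb$bins, names(counts))) counts[[b]] <- 0L
  counts <- counts[, c("region_id", tb$bins)]
  over <- as.matrix(counts[, tb$bins]) > min_occ_per_bin
  consec <- apply(over, 1, function(r) {
    any(r[-length(r)] & r[-1])
  })
  region_report <- counts |>
    dplyr::mutate(
      n_occurrences = rowSums(dplyr::pick(dplyr::all_of(tb$bins))),
      n_bins_over_threshold = rowSums(over),
      analyzable = consec | .data$region_id %in% whitelist
    ) |>
    dplyr::arrange(.data$region_id)
  list(assignment = assignment, regions = region_report)
}
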