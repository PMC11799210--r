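# Independent oracles used across the suite. These re-derive expected
# values from first principles (enumeration, brute force, closed forms)
# and must stay independent of the package code paths they check.

# exact one-tailed binomial tail probability by direct enumeration
oracle_binom_tail <- function(n_in, n_total, p0) {
  expected <- n_total * p0
  ks <- 0:n_total
  probs <- choose(n_total, ks) * p0^ks * (1 - p0)^(n_total - ks)
  if (n_in > expected) {
    sum(probs[ks >= n_in])
  } else if (n_in < expected) {
    sum(probs[ks <= n_in])
  } else {
    1
  }
}

# rule-table classification oracle: presence over (i-1, i, i+1, i+2) as
# logicals, fad/lad on the bin-index scale, positions at_i/at_i1 of bins
# i and i+1 on that scale; returns a level 1-5 or NA
oracle_classify <- function(p_im1, p_i, p_i1, p_i2, fad, lad,
                            at_i, at_i1, scheme) {
  if (scheme == "two_timer") {
    if (p_i && p_i1) return(3L)
    if (!p_i && p_i1 && p_i2) {
      return(if (!is.na(fad) && fad == at_i1) 1L else 2L)
    }
    if (p_im1 && p_i && !p_i1) {
      return(if (!is.na(lad) && lad == at_i) 5L else 4L)
    }
  } else {
    if (p_im1 && p_i && p_i1) return(3L)
    if (!p_im1 && p_i && p_i1) {
      return(if (!is.na(fad) && fad == at_i) 1L else 2L)
    }
    if (p_im1 && p_i && !p_i1) {
      return(if (!is.na(lad) && lad == at_i) 5L else 4L)
    }
  }
  NA_integer_
}

# brute-force nearest-unmasked-cell scan over the full search window
oracle_nearest <- function(field, lon, lat, radius) {
  haversine_m <- function(lon1, lat1, lon2, lat2) {
    r <- 6378137
    to_rad <- pi / 180
    dlat <- (lat2 - lat1) * to_rad
    dlon <- (lon2 - lon1) * to_rad
    a <- sin(dlat / 2)^2 +
      cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
    2 * r * asin(pmin(1, sqrt(a)))
  }
  step_lon <- diff(field$lon_axis)[1]
  step_lat <- diff(field$lat_axis)[1]
  i <- which(abs(field$lon_axis - lon) <= step_lon / 2)[1]
  j <- which(abs(field$lat_axis - lat) <= step_lat / 2)[1]
  if (is.na(i) || is.na(j)) return(NA_real_)
  if (!is.na(field$values[i, j])) return(field$values[i, j])
  rows <- NULL
  for (ci in max(1, i - radius):min(length(field$lon_axis), i + radius)) {
    for (cj in max(1, j - radius):min(length(field$lat_axis), j + radius)) {
      v <- field$values[ci, cj]
      if (is.na(v)) next
      rows <- rbind(rows, c(
        d = haversine_m(field$lon_axis[i], field$lat_axis[j],
                        field$lon_axis[ci], field$lat_axis[cj]),
        dlat = abs(field$lat_axis[cj] - field$lat_axis[j]),
        dlon = abs(field$lon_axis[ci] - field$lon_axis[i]),
        lon = field$lon_axis[ci], lat = field$lat_axis[cj], v = v))
    }
  }
  if (is.null(rows)) return(NA_real_)
  # nearest by distance; symmetric ties resolved by smaller |dlat|, then
  # smaller |dlon|, then westernmost, then southernmost
  best <- order(round(rows[, "d"], 6), rows[, "dlat"], rows[, "dlon"],
                rows[, "lon"], rows[, "lat"])[1]
  rows[best, "v"]
}

# step-by-step agglomerative clustering oracle (complete or average
# linkage) returning the k-group partition
oracle_hclust <- function(d, n, k, linkage = "complete") {
  dm <- as.matrix(d)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        pair_d <- dm[groups[[a]], groups[[b]], drop = FALSE]
        link <- if (linkage == "complete") max(pair_d) else mean(pair_d)
        if (link < best[1]) best <- c(link, a, b)
      }
    }
    merged <- c(groups[[best[2]]], groups[[best[3]]])
    groups <- groups[-c(best[2], best[3])]
    groups[[length(groups) + 1]] <- merged
  }
  out <- integer(n)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# small synthetic occurrence data frame for ingest tests
make_ingest_fixture <- function() {
  tibble::tibble(
    occurrence_no = 1:5,
    accepted_name = c("Gryphaea cymbium", " gryphaea   CYMBIUM ",
                      "Pseudopecten equivalvis", "Lobothyris punctata",
                      "Dactylioceras sp"),
    genus = c("Gryphaea", "Gryphaea", "Pseudopecten", "Lobothyris",
              "Dactylioceras"),
    clade = c("Bivalvia", "Bivalvia", "Bivalvia", "Rhynchonelliformea",
              "other"),
    lng = c(1, 2, 3, 4, 5), lat = c(45, 46, 47, 48, 49),
    paleolng_180 = c(10, 11, NA, 13, 14),
    paleolat_180 = c(30, 31, 32, 33, 34),
    paleolng_185 = c(9, 10, 11, 12, 13),
    paleolat_185 = c(29, 30, 31, 32, 33),
    zone = c("Spinatum", "Exaratum", "Bifrons", "Serpentinum",
             "NotAZone"),
    lithology1 = c("grainstone", "sandstone", "tuff", "limestone",
                   "shale"),
    environment = c("lagoonal", "offshore shelf", "cave", "reef rocks",
                    "offshore"),
    collection_no = 101:105
  )
}
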