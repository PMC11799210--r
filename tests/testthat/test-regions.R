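test_that("separated point clouds are recovered as clusters", {
  set.seed(1)
  cloud1 <- tibble::tibble(lon = rnorm(15, 0, 1), lat = rnorm(15, 30, 1))
  cloud2 <- tibble::tibble(lon = rnorm(15, 30, 1), lat = rnorm(15, 30, 1))
  pts <- dplyr::bind_rows(cloud1, cloud2)
  res <- cluster_spatial(pts, k = 2)
  lab1 <- res$region_id[res$lon < 15]
  lab2 <- res$region_id[res$lon > 15]
  expect_equal(length(unique(lab1)), 1)
  expect_equal(length(unique(lab2)), 1)
  expect_true(unique(lab1) != unique(lab2))
})

test_that("spatial clustering is invariant to row order and errors when k too big", {
  set.seed(2)
  pts <- tibble::tibble(lon = runif(20, 0, 40), lat = runif(20, 20, 50))
  a <- cluster_spatial(pts, k = 4)
  b <- cluster_spatial(pts[sample(20), ], k = 4)
  expect_equal(a, b)
  expect_error(cluster_spatial(pts[1:3, ], k = 5), "fewer distinct")
})

test_that("complete-linkage clustering equals the step-by-step merge oracle", {
  set.seed(3)
  pts <- tibble::tibble(lon = runif(12, 0, 50), lat = runif(12, 0, 50))
  res <- cluster_spatial(pts, k = 3, linkage = "complete")
  ordered <- dplyr::arrange(pts, lon, lat)
  want <- oracle_hclust(dist(as.matrix(ordered)), 12, 3, "complete")
  got <- res$region_id[match(paste(ordered$lon, ordered$lat),
                             paste(res$lon, res$lat))]
  # same partition up to relabelling
  expect_equal(partition_agreement(setNames(got, 1:12),
                                   setNames(want, 1:12))$agreement, 1)
})

test_that("disjoint faunal blocks separate and small clusters are filtered", {
  m <- matrix(0L, 20, 8,
              dimnames = list(sprintf("sp%02d", 1:20),
                              sprintf("loc%d", 1:8)))
  m[1:15, 1:4] <- 1L    # block A: 15 species
  m[16:20, 5:8] <- 1L   # block B: 5 species only
  res <- cluster_ecological(m, k = 2, min_species = 14)
  a <- res$region_id[1:4]; b <- res$region_id[5:8]
  expect_equal(length(unique(a)), 1)
  expect_false(any(is.na(a)))
  expect_true(all(is.na(b)))            # 5 < 14 species: removed
  expect_equal(unique(res$n_species_cluster[5:8]), 5)
  res_loose <- cluster_ecological(m, k = 2, min_species = 3)
  expect_false(any(is.na(res_loose$region_id)))
  expect_equal(length(unique(res_loose$region_id)), 2)
})

test_that("average-linkage Jaccard clustering matches the merge oracle", {
  set.seed(4)
  m <- matrix(rbinom(10 * 8, 1, 0.4), 10, 8,
              dimnames = list(sprintf("s%d", 1:10), sprintf("l%d", 1:8)))
  m[, 1] <- c(1, rep(0, 9))  # ensure no empty locality duplicates issues
  res <- cluster_ecological(m, k = 3, min_species = 1)
  d <- vegan::vegdist(t(m), method = "jaccard", binary = TRUE)
  want <- oracle_hclust(d, 8, 3, "average")
  expect_equal(partition_agreement(setNames(res$region_id, res$locality),
                                   setNames(want, res$locality))$agreement,
               1)
})

test_that("pair-counting agreement behaves as a Rand-type index", {
  ids <- letters[1:6]
  p1 <- setNames(c(1, 1, 1, 2, 2, 2), ids)
  expect_equal(partition_agreement(p1, p1)$agreement, 1)
  # relabelled copy still agrees perfectly
  p2 <- setNames(c(9, 9, 9, 4, 4, 4), ids)
  expect_equal(partition_agreement(p1, p2)$agreement, 1)
  # symmetric
  p3 <- setNames(c(1, 1, 2, 2, 2, 2), ids)
  expect_equal(partition_agreement(p1, p3)$agreement,
               partition_agreement(p3, p1)$agreement)
  # hand count for the one-element-moved variant: pairs = 15;
  # agreements: within {a,b} (1), within {d,e,f} (3), plus separated
  # pairs both keep apart: a-d a-e a-f b-d b-e b-f (6); c disagrees with
  # everything it touches except none -> c-a, c-b (together in p1, apart
  # in p3): disagree; c-d c-e c-f (apart in p1, together in p3): disagree
  expect_equal(partition_agreement(p1, p3)$agreement, 10 / 15)
  # singletons vs one block: no pair treated alike
  s <- setNames(1:5, letters[1:5])
  blk <- setNames(rep(1, 5), letters[1:5])
  expect_equal(partition_agreement(s, blk)$agreement, 0)
})

test_that("analyzable flags respect the strict occurrence threshold", {
  tb <- time_bins()
  mk_occ <- function(region, bin, n) {
    tibble::tibble(occurrence_id = paste0(region, bin, seq_len(n)),
                   time_bin = bin,
                   paleo_lon_primary = region * 10 + runif(n, -0.1, 0.1),
                   paleo_lat_primary = 30 + runif(n, -0.1, 0.1))
  }
  set.seed(5)
  occ <- dplyr::bind_rows(
    purrr::map_dfr(tb$bins, ~mk_occ(1, .x, 26)),  # all bins over threshold
    mk_occ(2, "Spinatum", 25), mk_occ(2, "Tenuicostatum", 25),
    mk_occ(3, "Margaritatus", 30), mk_occ(3, "Exaratum", 30)
  )
  regions <- cluster_spatial(
    tibble::tibble(lon = occ$paleo_lon_primary,
                   lat = occ$paleo_lat_primary), k = 3)
  res <- assign_regions(occ, regions, tb, min_occ_per_bin = 25)
  rep <- res$regions
  # identify regions by their lon neighbourhood via the assignment
  occ2 <- dplyr::left_join(occ, res$assignment, by = "occurrence_id")
  r1 <- unique(occ2$region_id[occ2$paleo_lon_primary < 15])
  r2 <- unique(occ2$region_id[occ2$paleo_lon_primary > 15 &
                                occ2$paleo_lon_primary < 25])
  r3 <- unique(occ2$region_id[occ2$paleo_lon_primary > 25])
  expect_true(rep$analyzable[rep$region_id == r1])
  expect_false(rep$analyzable[rep$region_id == r2])  # 25 is not > 25
  expect_false(rep$analyzable[rep$region_id == r3])  # not consecutive
  # whitelist overrides
  res_wl <- assign_regions(occ, regions, tb, min_occ_per_bin = 25,
                           whitelist = r3)
  expect_true(res_wl$regions$analyzable[res_wl$regions$region_id == r3])
  # partitions exhaustive: every occurrence assigned exactly once
  expect_equal(nrow(res$assignment), nrow(occ))
  expect_false(anyNA(res$assignment$region_id))
})
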