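#' Response level encoding
#'
#' Ordered occupancy-response levels: originating = 1, immigrating = 2,
#' persisting = 3, extirpated = 4, extinct = 5. Lower levels indicate a
#' species thermally well-suited to the new conditions (arriving), higher
#' levels one losing regional occupancy (and, at 5, its dataset-wide last
#' appearance).
#'
#' @return Named integer vector level-name -> code.
#' @export
response_levels <- function() {
  c(originating = 1L, immigrating = 2L, persisting = 3L,
    extirpated = 4L, extinct = 5L)
}

#' Classify per-region species occupancy responses around bin boundaries
#'
#' For every species x region x boundary (time i -> i + 1), assigns one of
#' the five ordered occupancy responses, or leaves the combination
#' unclassified, based on the regional presence pattern and the species'
#' dataset-wide first/last appearance (FAD/LAD).
#'
#' Two-timer scheme (default; change is pinned to the single focal
#' boundary):
#' * persisting (3): present in the region at i AND i + 1;
#' * immigrating (2): absent at i, present at i + 1 AND i + 2;
#'   originating (1) when additionally the global FAD is i + 1;
#' * extirpated (4): present at i - 1 AND i, absent at i + 1; extinct (5)
#'   when additionally the global LAD is i.
#'
#' Three-timer scheme:
#' * persisting (3): present at i - 1, i AND i + 1;
#' * immigrating (2): present at i AND i + 1, absent at i - 1;
#'   originating (1) when the global FAD is i;
#' * extirpated (4): present at i - 1 AND i, absent at i + 1; extinct (5)
#'   when the global LAD is i.
#'
#' Edge relaxation: where the i - 1 or i + 2 look-up falls in a flanking
#' bin (before the first or after the last analysed bin), the requirement
#' is satisfied by a presence anywhere in the dataset in that flanking bin,
#' regardless of region; a regional occurrence at i or i + 1 is still
#' required, so the relaxation admits species across the sampling
#' threshold without inventing regional signal.
#'
#' Species absent from the range table are classified at the non-extreme
#' level (immigrating rather than originating, extirpated rather than
#' extinct) with a warning.
#'
#' @param occurrences Tibble with `species`, `region_id`, `time_bin`
#'   (analysed-bin rows define regional presence; flanking-bin rows, any
#'   region, define the flanking global presences).
#' @param range_table Output of [compute_range_table()] on the global
#'   dataset; computed from `occurrences` when `NULL`.
#' @param tb A [time_bins()] object.
#' @param scheme "two_timer" (default) or "three_timer".
#' @return Tibble: `species`, `region_id`, `boundary`, `bin_i`, `bin_i1`,
#'   `level` (integer 1-5), `response` (name), `scheme`. Attribute
#'   `n_unclassified` counts species x region x boundary combinations with
#'   regional presence around the boundary that matched no rule.
#' @export
classify_occupancy <- function(occurrences, range_table = NULL,
                               tb = time_bins(),
                               scheme = c("two_timer", "three_timer")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("species", "region_id", "time_bin") %in%
                  names(occurrences)))
  if (is.null(range_table)) {
    range_table <- compute_range_table(occurrences, tb)
  }
  bins <- tb$bins
  B <- length(bins)

  empty <- tibble::tibble(species = character(), region_id = integer(),
                          boundary = character(), bin_i = character(),
                          bin_i1 = character(), level = integer(),
                          response = character(), scheme = character())
  pres <- occurrences |>
    dplyr::filter(.data$time_bin %in% bins) |>
    dplyr::distinct(.data$species, .data$region_id, .data$time_bin)
  sr <- dplyr::distinct(pres, .data$species, .data$region_id)
  if (nrow(sr) == 0) {
    attr(empty, "n_unclassified") <- 0L
    return(empty)
  }
  P <- matrix(FALSE, nrow(sr), B)
  row_of <- setNames(seq_len(nrow(sr)),
                     paste(sr$species, sr$region_id, sep = "\r"))
  P[cbind(row_of[paste(pres$species, pres$region_id, sep = "\r")],
          match(pres$time_bin, bins))] <- TRUE

  flank_before <- unique(
    occurrences$species[occurrences$time_bin == tb$flanking[1]])
  flank_after <- unique(
    occurrences$species[occurrences$time_bin == tb$flanking[2]])
  fb <- sr$species %in% flank_before
  fa <- sr$species %in% flank_after

  ridx <- match(sr$species, range_table$species)
  if (anyNA(ridx)) {
    warning(sum(is.na(ridx)), " species missing from range table; ",
            "classified at non-extreme levels")
  }
  fad <- range_table$fad_index[ridx]   # NA where missing
  lad <- range_table$lad_index[ridx]

  n_unclassified <- 0L
  res <- vector("list", B - 1L)
  lev_names <- names(response_levels())
  for (i in seq_len(B - 1L)) {
    p_i <- P[, i]
    p_i1 <- P[, i + 1L]
    p_im1 <- if (i - 1L >= 1L) P[, i - 1L] else fb
    p_i2 <- if (i + 2L <= B) P[, i + 2L] else fa
    # bin positions on the range-table index scale (leading flank = 0)
    at_i <- i
    at_i1 <- i + 1L

    if (scheme == "two_timer") {
      persisting <- p_i & p_i1
      immig <- !p_i & p_i1 & p_i2
      extirp <- p_im1 & p_i & !p_i1
    } else {
      persisting <- p_im1 & p_i & p_i1
      immig <- !p_im1 & p_i & p_i1
      extirp <- p_im1 & p_i & !p_i1
    }
    fad_at <- if (scheme == "two_timer") at_i1 else at_i
    orig <- immig & !is.na(fad) & fad == fad_at
    extinct <- extirp & !is.na(lad) & lad == at_i

    level <- rep(NA_integer_, nrow(sr))
    level[immig] <- 2L
    level[orig] <- 1L
    level[persisting] <- 3L
    level[extirp] <- 4L
    level[extinct] <- 5L
    # around-boundary presence with no matching rule
    n_unclassified <- n_unclassified +
      sum(is.na(level) & (p_i | p_i1))
    keep <- !is.na(level)
    if (any(keep)) {
      lv <- level[keep]
      res[[i]] <- tibble::tibble(
        species = sr$species[keep],
        region_id = sr$region_id[keep],
        boundary = paste0(bins[i], "->", bins[i + 1L]),
        bin_i = bins[i],
        bin_i1 = bins[i + 1L],
        level = lv,
        response = lev_names[lv],
        scheme = scheme
      )
    }
  }
  out <- dplyr::bind_rows(empty, res)
  attr(out, "n_unclassified") <- n_unclassified
  out
}

#' Attach thermal bias to response records
#'
#' Joins species temperature indices and regional median temperatures onto
#' classified responses and computes each record's thermal bias in its
#' context bin. Under the two-timer scheme the default context follows the
#' level: time i for persisting/extirpated/extinct species (levels 3-5,
#' whose fate is decided in the conditions they leave or endure), and time
#' i + 1 for immigrating/originating species (levels 1-2, whose arrival at
#' i + 1 is the event being explained). Three-timer records are always
#' contextualized at time i: in that scheme immigration is inferred from
#' absence at i - 1 and presence at i, so bin i is the arrival context for
#' every level. Records lacking an STI or a regional median are dropped
#' and counted in the `n_dropped_no_bias` attribute.
#'
#' @param records Output of [classify_occupancy()].
#' @param niches Output of [species_sti()] (`species`, `sti`).
#' @param climate Tibble `region_id`, `time_bin`, `median_t` (e.g.
#'   `regional_climate()$medians`).
#' @param context "by_level" (default, as above) or "bin_i" (all levels
#'   contextualized at time i).
#' @return `records` plus `sti`, `context_bin`, `ambient_t`,
#'   `thermal_bias`.
#' @export
attach_bias <- function(records, niches, climate,
                        context = c("by_level", "bin_i")) {
  context <- match.arg(context)
  stopifnot(all(c("species", "sti") %in% names(niches)),
            all(c("region_id", "time_bin", "median_t") %in% names(climate)))
  out <- records |>
    dplyr::mutate(context_bin = if (context == "bin_i") {
      .data$bin_i
    } else {
      ifelse(.data$level <= 2L & .data$scheme != "three_timer",
             .data$bin_i1, .data$bin_i)
    }) |>
    dplyr::left_join(dplyr::select(niches, "species", "sti"),
                     by = "species") |>
    dplyr::left_join(dplyr::select(climate, "region_id", "time_bin",
                                   ambient_t = "median_t"),
                     by = c("region_id", "context_bin" = "time_bin")) |>
    dplyr::mutate(thermal_bias = thermal_bias(.data$sti, .data$ambient_t))
  dropped <- sum(is.na(out$thermal_bias))
  out <- dplyr::filter(out, !is.na(.data$thermal_bias))
  attr(out, "n_dropped_no_bias") <- dropped
  out
}

#' Pool response levels for regression variants
#'
#' "merged" (default) treats extinctions conservatively as extirpations
#' and originations as immigrations (levels become 2, 3, 4);
#' "three_level" drops originating and extinct records entirely;
#' "five_level" keeps all five levels.
#'
#' @param records Response records with a `level` column.
#' @param pooling One of "merged", "five_level", "three_level".
#' @return `records` with a `level_pooled` column (and rows dropped under
#'   "three_level").
#' @export
pool_levels <- function(records,
                        pooling = c("merged", "five_level", "three_level")) {
  pooling <- match.arg(pooling)
  out <- switch(
    pooling,
    merged = dplyr::mutate(records,
                           level_pooled = pmin(pmax(.data$level, 2L), 4L)),
    five_level = dplyr::mutate(records, level_pooled = .data$level),
    three_level = records |>
      dplyr::filter(.data$level %in% 2:4) |>
      dplyr::mutate(level_pooled = .data$level)
  )
  out
}

#' Jaccard distance between two species sets
#'
#' `1 - |A intersect B| / |A union B|`; 0 for identical sets, 1 for
#' disjoint ones. Two empty sets have distance 0.
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard_distance(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Assemblage change summary per region and boundary
#'
#' Aggregates classified responses into the proportions used in
#' assemblage-level models: the percentage of the current (time-i)
#' assemblage classified as persisting, extirpated, or extinct (these sum
#' to 100 over classified current members), the percentage of the new
#' (time-i + 1) assemblage classified as immigrating or originating, and
#' the Jaccard turnover between the full regional species sets at i and
#' i + 1.
#'
#' @param records Output of [classify_occupancy()] (optionally with bias
#'   attached).
#' @param occurrences Occurrence tibble defining regional presence sets
#'   (`species`, `region_id`, `time_bin`).
#' @param tb A [time_bins()] object.
#' @return Tibble: `region_id`, `boundary`, `bin_i`, `bin_i1`, counts
#'   `n_originating` .. `n_extinct`, `pct_persisting`, `pct_extirpated`,
#'   `pct_extinct` (of classified current members), `pct_immigrating`,
#'   `pct_originating` (of classified new members), `jaccard_turnover`,
#'   `n_current`, `n_new`.
#' @export
summarize_assemblage <- function(records, occurrences, tb = time_bins()) {
  pres <- occurrences |>
    dplyr::filter(.data$time_bin %in% tb$bins) |>
    dplyr::distinct(.data$species, .data$region_id, .data$time_bin)
  counts <- records |>
    dplyr::count(.data$region_id, .data$boundary, .data$bin_i,
                 .data$bin_i1, .data$response) |>
    tidyr::pivot_wider(names_from = "response", values_from = "n",
                       values_fill = 0L)
  for (nm in names(response_levels())) {
    if (!nm %in% names(counts)) counts[[nm]] <- 0L
  }
  counts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      set_i = list(pres$species[pres$region_id == .data$region_id &
                                  pres$time_bin == .data$bin_i]),
      set_i1 = list(pres$species[pres$region_id == .data$region_id &
                                   pres$time_bin == .data$bin_i1]),
      n_current_classified = .data$persisting + .data$extirpated +
        .data$extinct,
      n_new_classified = .data$persisting + .data$immigrating +
        .data$originating,
      pct_persisting = 100 * .data$persisting /
        .data$n_current_classified,
      pct_extirpated = 100 * .data$extirpated /
        .data$n_current_classified,
      pct_extinct = 100 * .data$extinct / .data$n_current_classified,
      pct_immigrating = 100 * .data$immigrating / .data$n_new_classified,
      pct_originating = 100 * .data$originating / .data$n_new_classified,
      jaccard_turnover = jaccard_distance(.data$set_i, .data$set_i1),
      n_current = length(.data$set_i),
      n_new = length(.data$set_i1)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("region_id", "boundary", "bin_i", "bin_i1",
                  n_originating = "originating",
                  n_immigrating = "immigrating",
                  n_persisting = "persisting",
                  n_extirpated = "extirpated",
                  n_extinct = "extinct",
                  "pct_persisting", "pct_extirpated", "pct_extinct",
                  "pct_immigrating", "pct_originating",
                  "jaccard_turnover", "n_current", "n_new")
}
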