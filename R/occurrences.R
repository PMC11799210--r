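#' Normalize species names
#'
#' Conservative normalization: trim, collapse internal whitespace, and
#' lower-case, then apply an optional synonym table. No fuzzy matching is
#' attempted; taxonomic vetting beyond programmable synonymy is out of
#' scope.
#'
#' @param x Character vector of binomial names.
#' @param synonyms Optional data frame with columns `bad_name`,
#'   `accepted_name`; matched after normalization (both sides are
#'   normalized).
#' @return Character vector of normalized names.
#' @examples
#' normalize_species(c("  Gryphaea   Cymbium ", "gryphaea cymbium"))
#' @export
normalize_species <- function(x, synonyms = NULL) {
  out <- stringr::str_squish(tolower(as.character(x)))
  if (!is.null(synonyms)) {
    stopifnot(all(c("bad_name", "accepted_name") %in% names(synonyms)))
    bad <- stringr::str_squish(tolower(synonyms$bad_name))
    acc <- stringr::str_squish(tolower(synonyms$accepted_name))
    hit <- match(out, bad)
    out[!is.na(hit)] <- acc[hit[!is.na(hit)]]
  }
  out
}

#' Default column map for occurrence ingest
#'
#' Maps the package's canonical occurrence fields to the column names of a
#' delimited occurrence download. Override any entry to match other
#' dialects.
#'
#' @return Named character vector: canonical field -> source column name.
#' @export
occurrence_column_map <- function() {
  c(occurrence_id = "occurrence_no",
    species = "accepted_name",
    genus = "genus",
    clade = "clade",
    modern_lon = "lng",
    modern_lat = "lat",
    paleo_lon_primary = "paleolng_180",
    paleo_lat_primary = "paleolat_180",
    paleo_lon_secondary = "paleolng_185",
    paleo_lat_secondary = "paleolat_185",
    time_bin = "zone",
    lithology = "lithology1",
    environment = "environment",
    collection_id = "collection_no")
}

#' Read and normalize an occurrence table
#'
#' Ingests a delimited occurrence file (or an in-memory data frame in the
#' same layout), renames columns through a column map, normalizes species
#' names, resolves habitat categories via [categorize_habitat()], validates
#' coordinates and time bins, and returns the clean records together with
#' an ingest report. No record is invented: kept + dropped counts always
#' reconcile with the input row count.
#'
#' Rows are dropped (and counted by reason) when: primary paleocoordinates
#' are missing or out of range (`dropped_no_coords`); the time-bin label is
#' not in the configured bin sequence, flanking bins included
#' (`dropped_unmapped_bin`); or the label equals `undivided_label`
#' (default "Serpentinum"), a bin that the analysis resolution splits into
#' two subzones so that the undivided label cannot be placed
#' (`dropped_undivided`). Setting `undivided = "duplicate"` instead
#' duplicates such rows into both subzones for sensitivity runs.
#'
#' @param path Path to a delimited file, or a data frame already read.
#' @param column_map Named character vector (canonical -> source column);
#'   see [occurrence_column_map()]. `lithology`/`environment`/
#'   `collection_id`/secondary-coordinate entries are optional in the
#'   source; all other mapped columns must exist.
#' @param tb A [time_bins()] object defining valid bin labels.
#' @param synonyms Optional synonym table for [normalize_species()].
#' @param undivided One of "drop" (default) or "duplicate": what to do with
#'   rows labelled with `undivided_label`.
#' @param undivided_label Bin label that cannot be resolved to the analysis
#'   resolution; default "Serpentinum", whose occurrences belong to either
#'   the Exaratum or the Falciferum subzone.
#' @param undivided_into Length-2 character: the subzones a duplicated
#'   undivided row is copied into.
#' @param delim Field delimiter when `path` is a file; default ",".
#' @return A list with `records` (tibble of clean occurrence rows with
#'   canonical columns plus `lith_category`, `bath_category`) and `report`
#'   (named list of counts: `input_rows`, `kept`, `dropped_no_coords`,
#'   `dropped_unmapped_bin`, `dropped_undivided`, `duplicated_undivided`,
#'   plus `warnings`).
#' @export
read_occurrences <- function(path,
                             column_map = occurrence_column_map(),
                             tb = time_bins(),
                             synonyms = NULL,
                             undivided = c("drop", "duplicate"),
                             undivided_label = "Serpentinum",
                             undivided_into = c("Exaratum", "Falciferum"),
                             delim = ",") {
  undivided <- match.arg(undivided)
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("occurrence file not found: ", path,
                                 call. = FALSE)
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  warnings <- character()
  if (nrow(raw) == 0) warnings <- c(warnings, "empty occurrence source")

  mandatory <- c("occurrence_id", "species", "modern_lon", "modern_lat",
                 "paleo_lon_primary", "paleo_lat_primary", "time_bin")
  missing_cols <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  present <- column_map[unname(column_map) %in% names(raw)]
  dat <- raw |>
    dplyr::select(dplyr::all_of(unname(present))) |>
    rlang::set_names(names(present))
  for (opt in c("genus", "clade", "lithology", "environment",
                "collection_id")) {
    if (!opt %in% names(dat)) dat[[opt]] <- NA_character_
  }
  for (opt in c("paleo_lon_secondary", "paleo_lat_secondary")) {
    if (!opt %in% names(dat)) dat[[opt]] <- NA_real_
  }

  n_input <- nrow(dat)
  dat <- dat |>
    dplyr::mutate(
      species = normalize_species(.data$species, synonyms),
      dplyr::across(dplyr::all_of(c("modern_lon", "modern_lat",
                                    "paleo_lon_primary", "paleo_lat_primary",
                                    "paleo_lon_secondary",
                                    "paleo_lat_secondary")),
                    as.numeric),
      time_bin = stringr::str_squish(as.character(.data$time_bin))
    )

  coord_ok <- !is.na(dat$paleo_lon_primary) & !is.na(dat$paleo_lat_primary) &
    abs(dat$paleo_lon_primary) <= 180 & abs(dat$paleo_lat_primary) <= 90
  n_no_coords <- sum(!coord_ok)
  dat <- dat[coord_ok, , drop = FALSE]

  is_undivided <- dat$time_bin == undivided_label
  n_dup <- 0L
  n_undiv_dropped <- 0L
  if (any(is_undivided)) {
    if (undivided == "drop") {
      n_undiv_dropped <- sum(is_undivided)
      dat <- dat[!is_undivided, , drop = FALSE]
    } else {
      dup <- dat[is_undivided, , drop = FALSE]
      n_dup <- nrow(dup)
      dat <- dplyr::bind_rows(
        dat[!is_undivided, , drop = FALSE],
        dplyr::mutate(dup, time_bin = undivided_into[1]),
        dplyr::mutate(dup, time_bin = undivided_into[2])
      )
    }
  }

  valid_bins <- names(tb$index)
  bin_ok <- dat$time_bin %in% valid_bins
  n_bad_bin <- sum(!bin_ok)
  dat <- dat[bin_ok, , drop = FALSE]

  hab <- categorize_habitat(dat$lithology, dat$environment)
  records <- dplyr::bind_cols(dat, hab) |>
    dplyr::mutate(occurrence_id = as.character(.data$occurrence_id))

  report <- list(
    input_rows = n_input,
    kept = nrow(records),
    dropped_no_coords = n_no_coords,
    dropped_unmapped_bin = n_bad_bin,
    dropped_undivided = n_undiv_dropped,
    duplicated_undivided = n_dup,
    warnings = warnings
  )
  list(records = records, report = report)
}

#' Global first/last appearance table
#'
#' Computes each species' first (FAD) and last (LAD) appearance bin from a
#' dataset-wide occurrence set. FAD is the earliest bin with an occurrence
#' and LAD the latest, in the order defined by the bin sequence (flanking
#' bins participate so that range ends outside the analysis window are
#' honoured).
#'
#' @param occurrences Tibble with columns `species` and `time_bin`.
#' @param tb A [time_bins()] object.
#' @return Tibble: `species`, `fad_bin`, `lad_bin`, `fad_index`,
#'   `lad_index` (positions per [bin_index()]).
#' @examples
#' occ <- tibble::tibble(species = c("a sp", "a sp", "b sp"),
#'                       time_bin = c("Spinatum", "Exaratum", "Bifrons"))
#' compute_range_table(occ)
#' @export
compute_range_table <- function(occurrences, tb = time_bins()) {
  stopifnot(all(c("species", "time_bin") %in% names(occurrences)))
  idx <- bin_index(tb, occurrences$time_bin)
  if (anyNA(idx)) {
    stop("occurrences contain time bins outside the configured sequence",
         call. = FALSE)
  }
  occurrences |>
    dplyr::mutate(.idx = idx) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(fad_index = min(.data$.idx),
                     lad_index = max(.data$.idx), .groups = "drop") |>
    dplyr::mutate(
      fad_bin = names(tb$index)[match(.data$fad_index, tb$index)],
      lad_bin = names(tb$index)[match(.data$lad_index, tb$index)]
    ) |>
    dplyr::select("species", "fad_bin", "lad_bin", "fad_index", "lad_index")
}
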