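# single-species fixture builders around a focal boundary, shared by the
# classification unit tests and the acceptance suite

tb_default <- time_bins()

# occurrence table for one species in region 1 with regional presence at
# the given analysed-bin positions (1..6) and optional flanking-bin
# presences (anywhere in the dataset)
make_presence_occ <- function(bins_present, flank_before = FALSE,
                              flank_after = FALSE, species = "x") {
  rows <- tibble::tibble(species = species,
                         region_id = 1L,
                         time_bin = tb_default$bins[bins_present])
  if (flank_before) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      species = species, region_id = 99L,
      time_bin = tb_default$flanking[1]))
  }
  if (flank_after) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      species = species, region_id = 99L,
      time_bin = tb_default$flanking[2]))
  }
  rows
}

make_range <- function(fad_index, lad_index, species = "x") {
  tibble::tibble(species = species,
                 fad_bin = NA_character_, lad_bin = NA_character_,
                 fad_index = fad_index, lad_index = lad_index)
}

level_at <- function(records, boundary_i) {
  b <- paste0(tb_default$bins[boundary_i], "->",
              tb_default$bins[boundary_i + 1])
  lv <- records$level[records$boundary == b & records$species == "x"]
  if (length(lv) == 0) NA_integer_ else lv
}

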