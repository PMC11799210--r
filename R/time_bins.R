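#' Ordered time-bin sequences
#'
#' Analyses in this package run over an ordered sequence of time bins
#' (biostratigraphic zones, each roughly one million years long), plus two
#' flanking bins: the bin immediately before the first analysed bin and the
#' bin immediately after the last. The flanking bins are never analysed
#' themselves; they only supply the presences needed to classify occupancy
#' responses at the first and last bin boundary.
#'
#' The default sequence covers the late Pliensbachian to middle Toarcian
#' ammonite (sub)zones: Margaritatus, Spinatum, Tenuicostatum, Exaratum,
#' Falciferum, Bifrons, flanked by Davoei (before) and Variabilis (after).
#'
#' @param bins Character vector of bin labels in temporal order.
#' @param flanking Character vector of length 2: the labels of the bin
#'   preceding `bins[1]` and the bin following `bins[length(bins)]`.
#'
#' @return An object of class `time_bins`: a list with elements `bins`,
#'   `flanking`, and `index` (a named integer vector mapping every label,
#'   flanking included, to its position; the first analysed bin is 1, the
#'   leading flank 0, the trailing flank `length(bins) + 1`).
#' @examples
#' tb <- time_bins()
#' tb$bins
#' bin_index(tb, c("Spinatum", "Davoei"))
#' @export
time_bins <- function(bins = c("Margaritatus", "Spinatum", "Tenuicostatum",
                               "Exaratum", "Falciferum", "Bifrons"),
                      flanking = c("Davoei", "Variabilis")) {
  bins <- as.character(bins)
  flanking <- as.character(flanking)
  stopifnot(length(bins) >= 2, length(flanking) == 2)
  all_labels <- c(flanking[1], bins, flanking[2])
  if (anyDuplicated(all_labels)) {
    stop("time bin labels (including flanking bins) must be unique",
         call. = FALSE)
  }
  idx <- setNames(seq_along(all_labels) - 1L, all_labels)
  structure(list(bins = bins, flanking = flanking, index = idx),
            class = "time_bins")
}

#' @rdname time_bins
#' @param x A `time_bins` object.
#' @param labels Character vector of bin labels.
#' @export
bin_index <- function(x, labels) {
  stopifnot(inherits(x, "time_bins"))
  unname(x$index[as.character(labels)])
}

#' @export
print.time_bins <- function(x, ...) {
  cat("Time bins: ", paste(x$bins, collapse = " > "), "\n", sep = "")
  cat("Flanking:  ", x$flanking[1], " (before), ", x$flanking[2],
      " (after)\n", sep = "")
  invisible(x)
}

#' Bin-boundary labels for an ordered bin sequence
#'
#' @param tb A [time_bins()] object.
#' @return A tibble with one row per boundary between consecutive analysed
#'   bins: `boundary` ("bin_i->bin_i+1"), `bin_i`, `bin_i1`, and the integer
#'   position `i` of the earlier bin.
#' @examples
#' bin_boundaries(time_bins())
#' @export
bin_boundaries <- function(tb = time_bins()) {
  stopifnot(inherits(tb, "time_bins"))
  b <- tb$bins
  tibble::tibble(
    boundary = paste0(b[-length(b)], "->", b[-1]),
    bin_i = b[-length(b)],
    bin_i1 = b[-1],
    i = seq_len(length(b) - 1L)
  )
}
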