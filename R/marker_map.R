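#' Construct a marker map
#'
#' An ordered set of genetic markers along one chromosome, with positions in
#' centimorgans (cM) and the position of the centromere. Adjacent marker
#' pairs define the intervals used for tetrad classification; interval
#' lengths sum to the total genetic map length.
#'
#' @param markers character vector of marker names (unique, length >= 2).
#' @param positions_cM numeric vector of strictly increasing, non-negative
#'   genetic positions (cM), one per marker.
#' @param chromosome chromosome label.
#' @param centromere_cM genetic position of the centromere (cM); may
#'   coincide with a centromere-linked marker. Must lie within
#'   `[min(positions_cM), max(positions_cM)]`.
#'
#' @return An object of class `marker_map`: a list with elements `markers`,
#'   `positions_cM`, `chromosome`, `centromere_cM`, `centromere_index`
#'   (number of markers at or left of the centromere).
#' @examples
#' mm <- marker_map(c("A", "B", "C"), c(0, 10, 30), "III", centromere_cM = 10)
#' interval_lengths(mm)
#' @export
marker_map <- function(markers, positions_cM, chromosome = "chr",
                       centromere_cM = positions_cM[1]) {
  markers <- as.character(markers)
  positions_cM <- as.numeric(positions_cM)
  if (length(markers) < 2L)
    stop("a marker map needs at least two markers", call. = FALSE)
  if (length(markers) != length(positions_cM))
    stop("`markers` and `positions_cM` must have the same length", call. = FALSE)
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(positions_cM)) || any(positions_cM < 0))
    stop("marker positions must be finite and non-negative", call. = FALSE)
  if (any(diff(positions_cM) <= 0))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (!is.finite(centromere_cM) ||
      centromere_cM < positions_cM[1] ||
      centromere_cM > positions_cM[length(positions_cM)])
    stop("centromere position must lie within the marker span", call. = FALSE)
  structure(
    list(
      markers          = markers,
      positions_cM     = positions_cM,
      chromosome       = as.character(chromosome)[1],
      centromere_cM    = centromere_cM,
      centromere_index = sum(positions_cM <= centromere_cM)
    ),
    class = "marker_map"
  )
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: chromosome %s, %d markers, %.1f cM total\n",
              x$chromosome, length(x$markers), total_map_length(x)))
  cat(sprintf("  centromere at %.1f cM (after marker %d: %s)\n",
              x$centromere_cM, x$centromere_index,
              x$markers[x$centromere_index]))
  print(data.frame(marker = x$markers, position_cM = x$positions_cM),
        row.names = FALSE)
  invisible(x)
}

#' Interval names of a marker map
#'
#' Adjacent marker pairs, named `"left-right"`.
#' @param map a [marker_map()].
#' @return character vector of length `n_markers - 1`.
#' @export
interval_names <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  m <- map$markers
  paste(m[-length(m)], m[-1], sep = "-")
}

#' @rdname interval_names
#' @return for `interval_lengths`, a named numeric vector of interval
#'   lengths in cM.
#' @export
interval_lengths <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  stats::setNames(diff(map$positions_cM), interval_names(map))
}

#' @rdname interval_names
#' @return for `total_map_length`, the total map length in cM.
#' @export
total_map_length <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  sum(diff(map$positions_cM))
}

# Resolve a marker name (or index) to its index; error on unknown markers.
marker_index <- function(map, marker) {
  if (is.numeric(marker)) {
    idx <- as.integer(marker)
    if (any(idx < 1L | idx > length(map$markers)))
      stop("marker index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(marker, map$markers)
  if (anyNA(idx))
    stop("unknown marker(s): ", paste(marker[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

# Resolve an interval given as "A-B", c("A","B") or adjacent index to the
# pair of marker indices (i, j), i < j.
interval_index <- function(map, interval) {
  if (length(interval) == 1L && is.character(interval) &&
      grepl("-", interval, fixed = TRUE)) {
    hit <- match(interval, interval_names(map))
    if (!is.na(hit)) return(c(hit, hit + 1L))
    interval <- strsplit(interval, "-", fixed = TRUE)[[1]]
  }
  if (length(interval) == 1L && is.numeric(interval)) {
    i <- as.integer(interval)
    if (i < 1L || i >= length(map$markers))
      stop("interval index out of range", call. = FALSE)
    return(c(i, i + 1L))
  }
  if (length(interval) != 2L)
    stop("an interval is a marker pair", call. = FALSE)
  idx <- sort(marker_index(map, interval))
  if (idx[1] == idx[2])
    stop("an interval needs two distinct markers", call. = FALSE)
  idx
}

#' Default chromosome III marker configuration
#'
#' A nine-marker, eight-interval map spanning chromosome III, patterned on
#' the classical loci used to score crossing-over along the whole
#' chromosome, with allelic centromere-linked markers (`CEN3`) for disome
#' detection. Positions are plausible round-number spacings chosen so the
#' total equals 131.6 cM, a typical wild-type chromosome III genetic length;
#' they are a modelling default, not measured values.
#'
#' @return a [marker_map()] with markers HML, CHA1, TRP1, HIS4, CEN3, MAT,
#'   THR4, ABP1, HMR.
#' @examples
#' total_map_length(chr3_default_map())
#' @export
chr3_default_map <- function() {
  marker_map(
    markers = c("HML", "CHA1", "TRP1", "HIS4", "CEN3",
                "MAT", "THR4", "ABP1", "HMR"),
    positions_cM = c(0, 8, 21, 33, 46, 76, 97, 114, 131.6),
    chromosome = "III",
    centromere_cM = 46
  )
}
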