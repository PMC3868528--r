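#' A set of four-spore tetrads over a marker map
#'
#' The atomic observation of tetrad analysis: each tetrad is the four spores
#' of one meiosis, genotyped at every marker of a [marker_map()]. Marker
#' calls are parental-origin coded: `1` = P1, `2` = P2, `3` = BOTH (a
#' disomic spore carrying both parental alleles), `NA` = missing/unscorable.
#' An inviable spore's calls are treated as missing by every downstream
#' classifier.
#'
#' @param calls integer array with dimensions `c(4, n_markers, n_tetrads)`
#'   (spore, marker, tetrad), values in `{1, 2, 3, NA}`.
#' @param map a [marker_map()].
#' @param viable logical matrix `4 x n_tetrads`; defaults to all viable.
#' @param tetrad_id character vector of tetrad labels; defaults to
#'   `"t1" ... "tn"`.
#'
#' @return an object of class `tetrad_set`.
#' @examples
#' mm <- marker_map(c("A", "B"), c(0, 10))
#' # one parental-ditype tetrad
#' calls <- array(c(1, 1, 2, 2, 1, 1, 2, 2), dim = c(4, 2, 1))
#' ts <- tetrad_set(calls, mm)
#' classify_interval(ts, c("A", "B"))
#' @export
tetrad_set <- function(calls, map, viable = NULL, tetrad_id = NULL) {
  stopifnot(inherits(map, "marker_map"))
  if (!is.array(calls) || length(dim(calls)) != 3L || dim(calls)[1] != 4L)
    stop("`calls` must be a 4 x n_markers x n_tetrads array", call. = FALSE)
  if (dim(calls)[2] != length(map$markers))
    stop("`calls` has ", dim(calls)[2], " marker slices but the map has ",
         length(map$markers), " markers", call. = FALSE)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 1:3)
  if (any(bad))
    stop("marker calls must be 1 (P1), 2 (P2), 3 (BOTH) or NA", call. = FALSE)
  n <- dim(calls)[3]
  if (is.null(viable)) viable <- matrix(TRUE, 4L, n)
  viable <- matrix(as.logical(viable), 4L, n)
  if (anyNA(viable)) stop("`viable` must not contain NA", call. = FALSE)
  if (is.null(tetrad_id)) tetrad_id <- paste0("t", seq_len(n))
  tetrad_id <- as.character(tetrad_id)
  if (length(tetrad_id) != n)
    stop("`tetrad_id` must have one label per tetrad", call. = FALSE)
  if (anyDuplicated(tetrad_id))
    stop("duplicate tetrad ids", call. = FALSE)
  structure(
    list(calls = calls, viable = viable, tetrad_id = tetrad_id, map = map),
    class = "tetrad_set"
  )
}

#' @rdname tetrad_set
#' @param x,object a `tetrad_set`.
#' @export
n_tetrads <- function(x) {
  stopifnot(inherits(x, "tetrad_set"))
  dim(x$calls)[3]
}

#' Viable-spore count per tetrad
#' @param x a [tetrad_set()].
#' @return integer vector (0-4) per tetrad.
#' @export
n_viable <- function(x) {
  stopifnot(inherits(x, "tetrad_set"))
  as.integer(colSums(x$viable))
}

#' @export
print.tetrad_set <- function(x, ...) {
  cat(sprintf("tetrad_set: %d tetrads, %d markers on chromosome %s\n",
              n_tetrads(x), length(x$map$markers), x$map$chromosome))
  nv <- n_viable(x)
  cat(sprintf("  four-viable-spore tetrads: %d (%.1f%%)\n",
              sum(nv == 4L), 100 * mean(nv == 4L)))
  invisible(x)
}

#' @export
`[.tetrad_set` <- function(x, i, ...) {
  i <- seq_len(n_tetrads(x))[i]
  tetrad_set(x$calls[, , i, drop = FALSE], x$map,
             viable = x$viable[, i, drop = FALSE],
             tetrad_id = x$tetrad_id[i])
}

# Calls with inviable spores masked to NA: the view every classifier uses.
effective_calls <- function(x) {
  calls <- x$calls
  dead <- !x$viable                      # 4 x n
  if (any(dead)) {
    # expand the spore x tetrad mask across markers
    m <- dim(calls)[2]
    mask <- array(rep(dead, times = m), dim = c(4L, dim(calls)[3], m))
    mask <- aperm(mask, c(1, 3, 2))
    calls[mask] <- NA_integer_
  }
  calls
}

#' Score marker segregation in each tetrad
#'
#' Counts the P1:P2 segregation pattern of one marker among the four spores.
#' Mendelian segregation is 2:2; 3:1 and 1:3 patterns indicate gene
#' conversion; 4:0/0:4 are irregular. Any BOTH (disomic) or missing call —
#' including all calls of an inviable spore — forces `"aberrant"`.
#'
#' @param x a [tetrad_set()].
#' @param marker marker name or index.
#' @return character vector per tetrad, one of `"2:2"`, `"3:1"`, `"1:3"`,
#'   `"4:0"`, `"0:4"`, `"aberrant"`.
#' @examples
#' mm <- marker_map(c("A", "B"), c(0, 10))
#' calls <- array(c(1, 1, 1, 2, 1, 1, 2, 2), dim = c(4, 2, 1))
#' score_segregation(tetrad_set(calls, mm), "A")  # 3:1 conversion at A
#' @export
score_segregation <- function(x, marker) {
  stopifnot(inherits(x, "tetrad_set"))
  j <- marker_index(x$map, marker)
  if (length(j) != 1L) stop("score one marker at a time", call. = FALSE)
  cc <- effective_calls(x)[, j, , drop = TRUE]
  cc <- matrix(cc, nrow = 4L)            # 4 x n
  p1 <- colSums(cc == 1L, na.rm = TRUE)
  p2 <- colSums(cc == 2L, na.rm = TRUE)
  ok <- colSums(is.na(cc) | cc == 3L) == 0L
  out <- rep("aberrant", ncol(cc))
  out[ok] <- paste0(p1[ok], ":", p2[ok])
  out
}

# Logical matrix n_markers x n_tetrads: marker segregates 2:2 (no BOTH,
# no missing, two spores of each parental origin).
mendelian_matrix <- function(x) {
  cc <- effective_calls(x)
  m <- dim(cc)[2]; n <- dim(cc)[3]
  p1 <- apply(cc == 1L, c(2, 3), sum)
  clean <- apply(!is.na(cc) & cc != 3L, c(2, 3), all)
  matrix(clean & p1 == 2L, m, n)
}

#' Classify a tetrad's ditype for a marker pair
#'
#' The three tetrad classes of two-point tetrad analysis: parental ditype
#' (PD, all four spores parental for the pair), non-parental ditype (NPD,
#' all four recombinant — requires a four-strand double crossover) and
#' tetratype (TT, two parental and two recombinant). A tetrad is
#' `"UNSCORABLE"` for the pair when any relevant call is BOTH/missing or,
#' with `require_mendelian = TRUE` (the default), when either marker does
#' not segregate 2:2.
#'
#' Classification is symmetric in the order of the two markers.
#'
#' @param x a [tetrad_set()].
#' @param interval a marker pair: `c("A","B")`, `"A-B"`, or an adjacent
#'   interval index.
#' @param require_mendelian require 2:2 segregation at both markers
#'   (classical scoring); if `FALSE`, tetrads are classified purely by
#'   parental/recombinant spore counts where all calls are present.
#' @return character vector per tetrad: `"PD"`, `"NPD"`, `"TT"` or
#'   `"UNSCORABLE"`.
#' @export
classify_interval <- function(x, interval, require_mendelian = TRUE) {
  stopifnot(inherits(x, "tetrad_set"))
  ij <- interval_index(x$map, interval)
  cc <- effective_calls(x)
  ci <- matrix(cc[, ij[1], ], nrow = 4L)
  cj <- matrix(cc[, ij[2], ], nrow = 4L)
  clean <- !is.na(ci) & ci != 3L & !is.na(cj) & cj != 3L
  all_clean <- colSums(clean) == 4L
  parental <- colSums(clean & ci == cj)
  recomb <- colSums(clean & ci != cj)
  out <- rep("UNSCORABLE", ncol(ci))
  scorable <- all_clean
  if (require_mendelian) {
    # with all four calls clean, 2:2 at a marker is "exactly two P1 calls"
    scorable <- all_clean &
      colSums(ci == 1L, na.rm = TRUE) == 2L &
      colSums(cj == 1L, na.rm = TRUE) == 2L
  }
  out[scorable & parental == 4L] <- "PD"
  out[scorable & recomb == 4L] <- "NPD"
  out[scorable & parental == 2L & recomb == 2L] <- "TT"
  out
}

# Classify every adjacent interval: character matrix n_tetrads x n_intervals.
classify_all_intervals <- function(x, require_mendelian = TRUE) {
  iv <- interval_names(x$map)
  out <- vapply(seq_along(iv),
                function(k) classify_interval(x, k, require_mendelian),
                character(n_tetrads(x)))
  out <- matrix(out, nrow = n_tetrads(x),
                dimnames = list(x$tetrad_id, iv))
  out
}

#' Tally PD/NPD/TT counts per interval
#'
#' Aggregates ditype classes over a set of tetrads for every adjacent
#' interval of the map, under one of three filter policies:
#'
#' * `"paper"` (default): only tetrads with four viable spores and 2:2
#'   segregation at *every* map marker contribute — the classical filter for
#'   map-distance estimation; all other tetrads count as UNSCORABLE in every
#'   interval.
#' * `"lenient"`: per-interval scoring only — a tetrad contributes to any
#'   interval whose two flanking markers are clean and 2:2, regardless of
#'   other markers.
#' * `"none"`: no Mendelian requirement; tetrads are classified purely by
#'   parental/recombinant counts where calls are complete.
#'
#' @param x a [tetrad_set()].
#' @param filter_policy `"paper"`, `"lenient"` or `"none"`.
#' @return a data.frame of class `interval_tally` with columns `interval`,
#'   `PD`, `NPD`, `TT`, `n` (= PD+NPD+TT), `UNSCORABLE` and `length_cM`;
#'   attribute `n_tetrads` records the input size. For every interval
#'   `PD + NPD + TT + UNSCORABLE` equals the number of input tetrads.
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), n_tetrads = 100,
#'                                    seed = 1))
#' tally_intervals(sim$tetrads)
#' @export
tally_intervals <- function(x, filter_policy = c("paper", "lenient", "none")) {
  stopifnot(inherits(x, "tetrad_set"))
  filter_policy <- match.arg(filter_policy)
  n <- n_tetrads(x)
  if (n == 0L) stop("empty tetrad set", call. = FALSE)
  klass <- classify_all_intervals(x, require_mendelian =
                                    filter_policy != "none")
  if (filter_policy == "paper") {
    keep <- n_viable(x) == 4L & colSums(mendelian_matrix(x)) ==
      length(x$map$markers)
    klass[!keep, ] <- "UNSCORABLE"
  }
  tab <- apply(klass, 2, function(k)
    c(PD = sum(k == "PD"), NPD = sum(k == "NPD"), TT = sum(k == "TT"),
      UNSCORABLE = sum(k == "UNSCORABLE")))
  out <- data.frame(
    interval = colnames(klass),
    PD = tab["PD", ], NPD = tab["NPD", ], TT = tab["TT", ],
    n = tab["PD", ] + tab["NPD", ] + tab["TT", ],
    UNSCORABLE = tab["UNSCORABLE", ],
    length_cM = unname(interval_lengths(x$map)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_tetrads") <- n
  attr(out, "filter_policy") <- filter_policy
  class(out) <- c("interval_tally", "data.frame")
  out
}

#' Build a single interval tally from counts
#'
#' Convenience constructor for estimators that take published PD/NPD/TT
#' counts directly rather than raw tetrads.
#'
#' @param PD,NPD,TT non-negative integer counts.
#' @param interval optional interval label.
#' @return an `interval_tally` with one row.
#' @examples
#' perkins_cM(interval_tally(PD = 70, NPD = 2, TT = 28))
#' @export
interval_tally <- function(PD, NPD, TT, interval = "interval") {
  stopifnot(length(PD) == length(NPD), length(NPD) == length(TT))
  if (any(c(PD, NPD, TT) < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- data.frame(interval = interval, PD = PD, NPD = NPD, TT = TT,
                    n = PD + NPD + TT, UNSCORABLE = 0L,
                    length_cM = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("interval_tally", "data.frame")
  out
}
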