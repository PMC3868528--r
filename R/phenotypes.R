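#' Spore-viability distribution
#'
#' Tallies tetrads by number of viable spores (4, 3, 2, 1, 0) and computes
#' overall spore viability. A preponderance of two- and zero-viable-spore
#' tetrads is the classical signature of meiosis I nondisjunction, which
#' sends both homologs of a chromosome to the same pole and so kills spores
#' in pairs.
#'
#' @param x a [tetrad_set()], or a named/unnamed integer vector of tetrad
#'   counts per viability class ordered 4, 3, 2, 1, 0 viable spores.
#' @return object of class `viability_distribution`: list with `counts`
#'   (named vector `v4 ... v0`), `n_tetrads`, `total_spores`,
#'   `viable_spores`, `viability_pct` (= 100 * viable/total, unrounded).
#' @examples
#' viability_distribution(c(v4 = 3, v3 = 0, v2 = 0, v1 = 0, v0 = 0))
#' @export
viability_distribution <- function(x) {
  if (inherits(x, "tetrad_set")) {
    nv <- n_viable(x)
    counts <- vapply(4:0, function(k) sum(nv == k), integer(1))
  } else {
    if (length(x) != 5L)
      stop("supply counts for 4,3,2,1,0 viable-spore classes", call. = FALSE)
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    counts <- as.integer(x)
  }
  names(counts) <- paste0("v", 4:0)
  n <- sum(counts)
  viable <- sum(counts * (4:0))
  structure(
    list(counts = counts, n_tetrads = n, total_spores = 4L * n,
         viable_spores = viable,
         viability_pct = if (n > 0) 100 * viable / (4 * n) else NA_real_),
    class = "viability_distribution"
  )
}

#' @export
print.viability_distribution <- function(x, ...) {
  cat(sprintf("spore viability: %d/%d (%.1f%%) over %d tetrads\n",
              x$viable_spores, x$total_spores, x$viability_pct, x$n_tetrads))
  print(x$counts)
  invisible(x)
}

#' Detect disomic spores via centromere-linked heteroalleles
#'
#' A spore disomic for the chromosome carries both parental homologs and
#' therefore both alleles of allelic, centromere-linked markers (call BOTH
#' at each). Tetrads with at least one such spore are flagged as meiosis I
#' nondisjunction events. Fractions are computed over genotypable tetrads:
#' those with at least one viable spore scorable at both markers.
#'
#' @param x a [tetrad_set()].
#' @param cen_markers the centromere-linked marker name(s) — typically a
#'   pair of allelic heteroalleles scored as one or two map columns. A
#'   warning is issued if any lies more than 5 cM from the map's centromere.
#' @return object of class `disome_scoring`: list with `records` (data.frame
#'   `tetrad_id`, `disomic_spores`, for flagged tetrads), `n_flagged`,
#'   `n_genotypable`, `fraction`.
#' @examples
#' mm <- chr3_default_map()
#' sim <- simulate_tetrads(sim_config(mm, n_tetrads = 500,
#'                                    assurance_fail_q = 0.2,
#'                                    backup_efficiency_b = 0.5, seed = 1))
#' score_disomes(sim$tetrads, "CEN3")
#' @export
score_disomes <- function(x, cen_markers) {
  stopifnot(inherits(x, "tetrad_set"))
  idx <- unique(marker_index(x$map, cen_markers))
  pos <- x$map$positions_cM[idx]
  if (any(abs(pos - x$map$centromere_cM) > 5))
    warning("marker(s) ", paste(x$map$markers[idx], collapse = ", "),
            " lie > 5 cM from the centromere; disome scoring assumes ",
            "centromere linkage", call. = FALSE)
  cc <- effective_calls(x)
  # spore is disomic iff BOTH at every designated centromere-linked marker
  dis <- apply(cc[, idx, , drop = FALSE] == 3L, c(1, 3), all)   # 4 x n
  dis[is.na(dis)] <- FALSE
  # genotypable: >= 1 viable spore with calls present at all cen markers
  scorable <- apply(!is.na(cc[, idx, , drop = FALSE]), c(1, 3), all)
  genotypable <- colSums(scorable) > 0L
  flagged <- colSums(dis) > 0L & genotypable
  spore_names <- c("a", "b", "c", "d")
  records <- data.frame(
    tetrad_id = x$tetrad_id[flagged],
    disomic_spores = vapply(which(flagged), function(j)
      paste(spore_names[dis[, j]], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(records = records, n_flagged = sum(flagged),
         n_genotypable = sum(genotypable),
         fraction = sum(flagged) / sum(genotypable)),
    class = "disome_scoring"
  )
}

#' @export
print.disome_scoring <- function(x, ...) {
  cat(sprintf("disomic tetrads: %d/%d (%.2f%%)\n",
              x$n_flagged, x$n_genotypable, 100 * x$fraction))
  invisible(x)
}

#' Gene conversion per tetrad
#'
#' A tetrad shows gene conversion when any map marker segregates 3:1 or 1:3
#' (non-reciprocal transfer). 4:0 and 0:4 patterns are reported separately
#' as irregular rather than counted as conversions.
#'
#' @param x a [tetrad_set()].
#' @return data.frame per tetrad: `tetrad_id`, `n_converted_markers`,
#'   `conversion` (any 3:1/1:3), `irregular` (any 4:0/0:4).
#' @export
conversion_per_tetrad <- function(x) {
  stopifnot(inherits(x, "tetrad_set"))
  seg <- vapply(seq_along(x$map$markers),
                function(j) score_segregation(x, j),
                character(n_tetrads(x)))
  seg <- matrix(seg, nrow = n_tetrads(x))
  conv <- seg == "3:1" | seg == "1:3"
  irr <- seg == "4:0" | seg == "0:4"
  data.frame(
    tetrad_id = x$tetrad_id,
    n_converted_markers = rowSums(conv),
    conversion = rowSums(conv) > 0L,
    irregular = rowSums(irr) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate gene conversion against exchange status
#'
#' Classifies each tetrad as E0 (no crossover in any scorable interval) or
#' exchange, and as showing gene conversion (any 3:1/1:3 marker) or not,
#' then tests the association with Fisher's exact test. Exchange status is
#' computed on scorable intervals (`drop_policy = "use_scorable"`), because
#' a converted marker renders its flanking intervals unscorable and would
#' otherwise eject every converted tetrad from the cross-tab.
#'
#' @param x a [tetrad_set()].
#' @return object of class `conversion_crosstab`: list with `table` (2x2:
#'   exchange status x conversion), `fractions` (conversion fraction within
#'   E0, within exchange, and overall), `p_value` (Fisher), `n`.
#' @export
conversion_crosstab <- function(x) {
  stopifnot(inherits(x, "tetrad_set"))
  cc <- crossover_classes(x, drop_policy = "use_scorable")
  conv <- conversion_per_tetrad(x)
  keep <- match(names(cc$per_tetrad), conv$tetrad_id)
  status <- factor(ifelse(cc$per_tetrad == 0L, "E0", "exchange"),
                   levels = c("E0", "exchange"))
  convf <- factor(ifelse(conv$conversion[keep], "conversion", "none"),
                  levels = c("conversion", "none"))
  tab <- table(status, convf)
  p <- if (all(dim(tab) == c(2L, 2L)) && sum(tab) > 0)
    stats::fisher.test(tab)$p.value else NA_real_
  structure(
    list(table = tab,
         fractions = c(
           E0 = unname(tab["E0", "conversion"] / sum(tab["E0", ])),
           exchange = unname(tab["exchange", "conversion"] /
                               sum(tab["exchange", ])),
           overall = unname(sum(tab[, "conversion"]) / sum(tab))),
         p_value = p, n = sum(tab)),
    class = "conversion_crosstab"
  )
}

#' @export
print.conversion_crosstab <- function(x, ...) {
  cat("gene conversion x exchange status\n")
  print(x$table)
  cat(sprintf(
    "  conversion fraction: E0 %.2f%%, exchange %.2f%%, overall %.2f%% (Fisher p = %.4g)\n",
    100 * x$fractions["E0"], 100 * x$fractions["exchange"],
    100 * x$fractions["overall"], x$p_value))
  invisible(x)
}
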