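#' Perkins map distance
#'
#' Two-point tetrad map distance correcting for double crossovers:
#' \deqn{cM = \frac{100\,(6\,NPD + TT)}{2\,(PD + NPD + TT)}}
#' equivalently `100 * (TT/2 + 3*NPD) / n`. The standard error is the
#' multinomial delta-method value: writing the estimate as
#' `50*(6*pNPD + pTT)` in the class proportions,
#' `se = sqrt((50^2*pTT + 300^2*pNPD - cM^2)/n)`.
#'
#' @param tally an `interval_tally` (one or more rows), e.g. from
#'   [tally_intervals()] or [interval_tally()].
#' @return the tally with columns `cM` and `se_cM` appended.
#' @examples
#' perkins_cM(interval_tally(PD = 70, NPD = 2, TT = 28))  # 20 cM
#' @export
perkins_cM <- function(tally) {
  tally <- as.data.frame(tally)
  stopifnot(all(c("PD", "NPD", "TT") %in% names(tally)))
  n <- tally$PD + tally$NPD + tally$TT
  if (any(n < 1L)) stop("need PD + NPD + TT >= 1", call. = FALSE)
  cM <- 100 * (6 * tally$NPD + tally$TT) / (2 * n)
  pT <- tally$TT / n
  pN <- tally$NPD / n
  var_cM <- (50^2 * pT + 300^2 * pN - cM^2) / n
  tally$n <- n
  tally$cM <- cM
  tally$se_cM <- sqrt(pmax(var_cM, 0))
  class(tally) <- c("interval_tally", "data.frame")
  tally
}

#' Expected NPD frequency in the absence of interference
#'
#' Papazian's expectation for the non-parental-ditype frequency given the
#' observed tetratype frequency `fT`, assuming crossovers without
#' interference and no chromatid interference:
#' \deqn{NPD_{exp} = \tfrac{1}{2}\left[(1 - f_T) - (1 - 3 f_T/2)^{2/3}\right]}
#' The expectation is defined on `0 <= fT <= 2/3` (fT = 2/3 is the
#' many-crossover limit). Values outside the domain return `NA` with a
#' warning rather than being clamped: an observed tetratype frequency above
#' 2/3 signals data inconsistency, not a computable expectation.
#'
#' @param fT tetratype frequency (vectorised).
#' @return expected NPD frequency, non-negative on the domain.
#' @examples
#' papazian_expected_npd(0.4)        # ~0.0286
#' papazian_expected_npd(2 / 3)      # 1/6
#' @export
papazian_expected_npd <- function(fT) {
  out <- rep(NA_real_, length(fT))
  bad <- !is.na(fT) & (fT < 0 | fT > 2 / 3)
  if (any(bad))
    warning("tetratype frequency outside [0, 2/3]; expected NPD undefined",
            call. = FALSE)
  ok <- !is.na(fT) & !bad
  out[ok] <- 0.5 * ((1 - fT[ok]) - (1 - 3 * fT[ok] / 2)^(2 / 3))
  # guard tiny negative rounding at fT ~ 0
  out[ok] <- pmax(out[ok], 0)
  out
}

#' NPD ratio: observed over expected non-parental ditypes
#'
#' The classical single-interval interference statistic: the observed NPD
#' frequency divided by the Papazian no-interference expectation computed
#' from the tetratype frequency. Ratios significantly below 1 indicate
#' positive crossover interference. Significance is a one-sided exact
#' binomial test of the observed NPD count against the expected frequency
#' (default alternative `"less"`, i.e. testing for positive interference).
#'
#' @param tally an `interval_tally` (one or more rows).
#' @param alternative alternative hypothesis for the binomial test:
#'   `"less"` (positive interference), `"greater"`, or `"two.sided"`.
#' @return data.frame with columns `interval`, `n`, `NPD_obs`, `fT`,
#'   `NPD_exp_freq`, `NPD_exp_count`, `npd_ratio`, `p_value`. The ratio is
#'   `NA` when the Papazian expectation is undefined (fT outside its
#'   domain), `Inf` when the expectation is 0 but NPDs were observed, and 0
#'   when no NPDs were observed.
#' @examples
#' npd_ratio(interval_tally(PD = 70, NPD = 2, TT = 28))  # ratio ~1.63
#' @export
npd_ratio <- function(tally, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tally <- as.data.frame(tally)
  n <- tally$PD + tally$NPD + tally$TT
  if (any(n < 1L)) stop("need PD + NPD + TT >= 1", call. = FALSE)
  fT <- tally$TT / n
  expct <- suppressWarnings(papazian_expected_npd(fT))
  domain_ok <- !is.na(expct)
  if (!all(domain_ok))
    warning("tetratype frequency outside [0, 2/3] in ",
            sum(!domain_ok), " interval(s); NPD ratio undefined there",
            call. = FALSE)
  obs <- tally$NPD / n
  ratio <- ifelse(domain_ok,
                  ifelse(expct > 0, obs / expct,
                         ifelse(obs > 0, Inf, NaN)),
                  NA_real_)
  p <- rep(NA_real_, length(n))
  for (i in seq_along(n)) {
    if (domain_ok[i] && expct[i] > 0 && expct[i] < 1) {
      p[i] <- stats::binom.test(tally$NPD[i], n[i], p = expct[i],
                                alternative = alternative)$p.value
    }
  }
  data.frame(
    interval = if (!is.null(tally$interval)) tally$interval else
      paste0("iv", seq_along(n)),
    n = n, NPD_obs = tally$NPD, fT = fT,
    NPD_exp_freq = expct, NPD_exp_count = expct * n,
    npd_ratio = ratio, p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Adjacent-interval interference
#'
#' Coincidence-style interference between two genetic intervals. Tetrads are
#' split by their class in the reference interval into those with a
#' crossover (AdjCO: TT or NPD) and those without (AdjPD: PD); the Perkins
#' map distance of the test interval is then computed within each subset and
#' interference is expressed as the ratio `cM(AdjCO) / cM(AdjPD)`. Ratios
#' below 1 indicate positive interference. The reported statistic is the
#' mean of the two ratios obtained by swapping the reference and test roles
#' (reciprocal analysis).
#'
#' Significance is assessed by a permutation test: the reference-interval
#' classes are permuted across tetrads (breaking any association between the
#' two intervals while preserving both margins) and the mean reciprocal
#' ratio recomputed; the one-sided p-value is the fraction of permutations
#' with a ratio at least as small as observed (`(k + 1) / (n_perm + 1)`).
#' A chi-squared test on the 2x3 (AdjCO/AdjPD x PD/TT/NPD) contingency
#' table is reported as a cross-check.
#'
#' @param x a [tetrad_set()].
#' @param ref_interval,test_interval interval specifications (see
#'   [classify_interval()]).
#' @param n_perm number of label permutations (0 skips the permutation
#'   test).
#' @param require_mendelian passed to [classify_interval()].
#' @return list of class `adjacent_interference` with elements `adj_ratio`
#'   (mean of the two reciprocal ratios), `ratio_fwd`, `ratio_rev`,
#'   `p_value` (permutation), `p_chisq`, `subset_sizes`, `table` (the 2x3
#'   table for the forward orientation) and `undefined` flag (TRUE when a
#'   subset is empty or a denominator distance is 0).
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), n_tetrads = 2000,
#'                                    interference_m = 3, obligate_CO = TRUE,
#'                                    seed = 1))
#' adjacent_interference(sim$tetrads, "CEN3-MAT", "MAT-THR4", n_perm = 500)
#' @export
adjacent_interference <- function(x, ref_interval, test_interval,
                                  n_perm = 10000, require_mendelian = TRUE) {
  stopifnot(inherits(x, "tetrad_set"))
  ref <- classify_interval(x, ref_interval, require_mendelian)
  tst <- classify_interval(x, test_interval, require_mendelian)
  keep <- ref != "UNSCORABLE" & tst != "UNSCORABLE"
  ref <- ref[keep]; tst <- tst[keep]
  one_way <- function(a, b) {
    co <- a != "PD"
    n_co <- sum(co); n_pd <- sum(!co)
    if (n_co == 0L || n_pd == 0L) return(NA_real_)
    d_co <- mean_perkins(b[co])
    d_pd <- mean_perkins(b[!co])
    if (d_pd == 0) return(if (d_co == 0) NaN else NA_real_)
    d_co / d_pd
  }
  r_fwd <- one_way(ref, tst)
  r_rev <- one_way(tst, ref)
  adj <- mean(c(r_fwd, r_rev))
  undefined <- !is.finite(adj)
  tab <- table(factor(ifelse(ref == "PD", "AdjPD", "AdjCO"),
                      levels = c("AdjCO", "AdjPD")),
               factor(tst, levels = c("PD", "TT", "NPD")))
  p_chisq <- tryCatch(
    suppressWarnings(stats::chisq.test(tab[, colSums(tab) > 0,
                                           drop = FALSE])$p.value),
    error = function(e) NA_real_)
  p_perm <- NA_real_
  if (n_perm > 0 && !undefined) {
    stat <- numeric(n_perm)
    n <- length(ref)
    for (k in seq_len(n_perm)) {
      rp <- ref[sample.int(n)]
      stat[k] <- mean(c(one_way(rp, tst), one_way(tst, rp)))
    }
    ok <- is.finite(stat)
    p_perm <- (sum(stat[ok] <= adj) + 1) / (sum(ok) + 1)
  }
  structure(
    list(ref_interval = format_interval(x$map, ref_interval),
         test_interval = format_interval(x$map, test_interval),
         adj_ratio = adj, ratio_fwd = r_fwd, ratio_rev = r_rev,
         p_value = p_perm, p_chisq = p_chisq,
         subset_sizes = c(AdjCO = sum(ref != "PD"), AdjPD = sum(ref == "PD")),
         table = tab, n_perm = n_perm, undefined = undefined),
    class = "adjacent_interference"
  )
}

# Perkins distance from a vector of PD/NPD/TT class labels.
mean_perkins <- function(klass) {
  n <- length(klass)
  100 * (6 * sum(klass == "NPD") + sum(klass == "TT")) / (2 * n)
}

format_interval <- function(map, interval) {
  ij <- interval_index(map, interval)
  paste(map$markers[ij], collapse = "-")
}

#' @export
print.adjacent_interference <- function(x, ...) {
  cat(sprintf("adjacent-interval interference: ref %s, test %s\n",
              x$ref_interval, x$test_interval))
  cat(sprintf("  Adj^CO/Adj^PD ratio (reciprocal mean): %.3f  (fwd %.3f, rev %.3f)\n",
              x$adj_ratio, x$ratio_fwd, x$ratio_rev))
  cat(sprintf("  subsets: AdjCO = %d, AdjPD = %d\n",
              x$subset_sizes["AdjCO"], x$subset_sizes["AdjPD"]))
  if (!is.na(x$p_value))
    cat(sprintf("  permutation p (ratio < 1): %.4g  [%d perms]; chi-sq p: %.4g\n",
                x$p_value, x$n_perm, x$p_chisq))
  invisible(x)
}

#' Chromosome crossover-class distribution
#'
#' Reconstructs, per tetrad, the minimal number of crossovers along the
#' chromosome as the sum over adjacent intervals of 0 (PD), 1 (TT) or 2
#' (NPD — a four-strand double crossover), and tabulates tetrads into
#' exchange classes E0, E1, ..., Ek. This minimal reconstruction undercounts
#' intervals containing multiple crossovers; it is the standard convention
#' for E-class tallies. E0 tetrads — no crossover anywhere on the chromosome
#' — are the non-exchange class central to crossover-assurance analysis.
#'
#' @param x a [tetrad_set()].
#' @param drop_policy `"any_unscorable"` (default): tetrads with any
#'   unscorable interval are dropped from the distribution and reported;
#'   `"use_scorable"`: tetrads are classified on their scorable intervals
#'   (dropped only if none is scorable).
#' @return object of class `crossover_classes`: list with `counts` (named
#'   vector E0...Ek), `n`, `n_dropped`, `mean_CO` (= sum(i * Ei) / n) and
#'   `per_tetrad` (integer crossover count per retained tetrad, named by
#'   tetrad id).
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), n_tetrads = 500,
#'                                    seed = 1))
#' crossover_classes(sim$tetrads)
#' @export
crossover_classes <- function(x, drop_policy = c("any_unscorable",
                                                 "use_scorable")) {
  stopifnot(inherits(x, "tetrad_set"))
  drop_policy <- match.arg(drop_policy)
  klass <- classify_all_intervals(x)
  score <- matrix(c(PD = 0L, TT = 1L, NPD = 2L, UNSCORABLE = NA_integer_)[klass],
                  nrow = nrow(klass), dimnames = dimnames(klass))
  if (drop_policy == "any_unscorable") {
    keep <- rowSums(is.na(score)) == 0L
    co <- rowSums(score)[keep]
  } else {
    keep <- rowSums(!is.na(score)) > 0L
    co <- rowSums(score, na.rm = TRUE)[keep]
  }
  counts <- table(factor(co, levels = 0:max(c(co, 0))))
  names(counts) <- paste0("E", names(counts))
  n <- sum(counts)
  structure(
    list(counts = c(counts), n = n, n_dropped = sum(!keep),
         mean_CO = if (n > 0) sum(co) / n else NA_real_,
         per_tetrad = co),
    class = "crossover_classes"
  )
}

#' Build a crossover-class distribution from counts
#'
#' For published E-class tallies where per-tetrad data are unavailable.
#'
#' @param counts named (`E0`, `E1`, ...) or unnamed (E0 first) non-negative
#'   integer vector.
#' @return a `crossover_classes` object.
#' @examples
#' crossover_class_counts(c(E0 = 9, E1 = 300, E2 = 500, E3 = 230))
#' @export
crossover_class_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- paste0("E", seq_along(counts) - 1)
  k <- as.integer(sub("^E", "", names(counts)))
  if (anyNA(k)) stop("names must be E0, E1, ...", call. = FALSE)
  n <- sum(counts)
  structure(
    list(counts = counts, n = n, n_dropped = 0L,
         mean_CO = sum(k * counts) / n, per_tetrad = NULL),
    class = "crossover_classes"
  )
}

#' @export
print.crossover_classes <- function(x, ...) {
  cat(sprintf("crossover classes over %d tetrads (%d dropped as unscorable)\n",
              x$n, x$n_dropped))
  print(x$counts)
  cat(sprintf("  E0 fraction: %.4f; mean crossovers per tetrad: %.3f\n",
              e0_fraction(x), x$mean_CO))
  invisible(x)
}

#' @rdname crossover_classes
#' @param dist a `crossover_classes` object.
#' @export
e0_fraction <- function(dist) {
  stopifnot(inherits(dist, "crossover_classes"))
  unname(dist$counts["E0"] / dist$n)
}

#' Crossover assurance test against a Poisson null
#'
#' Under random (Poisson) placement of crossovers with mean `mean_CO` per
#' bivalent, the expected fraction of non-exchange (E0) tetrads is
#' `exp(-mean_CO)`. Crossover assurance drives the observed E0 fraction
#' below this expectation; assurance failure drives it above. The test is a
#' one-sided exact binomial test of the observed E0 count; with
#' `alternative = "auto"` (default) the side is the direction of the
#' observed departure.
#'
#' @param dist a `crossover_classes` object.
#' @param mean_CO Poisson mean; defaults to the distribution's own mean.
#' @param alternative `"auto"`, `"less"`, `"greater"` or `"two.sided"`.
#' @return list of class `assurance_test`: `E0_obs`, `n`, `E0_frac_obs`,
#'   `E0_frac_exp` (= exp(-mean_CO)), `mean_CO`, `p_value`, `alternative`.
#' @examples
#' d <- crossover_class_counts(c(E0 = 210, E1 = 500, E2 = 400, E3 = 266))
#' assurance_test(d, mean_CO = cM_to_mean_CO(116.8))
#' @export
assurance_test <- function(dist, mean_CO = dist$mean_CO,
                           alternative = c("auto", "less", "greater",
                                           "two.sided")) {
  stopifnot(inherits(dist, "crossover_classes"))
  alternative <- match.arg(alternative)
  if (!is.finite(mean_CO) || mean_CO < 0)
    stop("`mean_CO` must be a non-negative number", call. = FALSE)
  expct <- exp(-mean_CO)
  e0 <- unname(dist$counts["E0"])
  if (alternative == "auto")
    alternative <- if (e0 / dist$n >= expct) "greater" else "less"
  p <- stats::binom.test(e0, dist$n, p = expct,
                         alternative = alternative)$p.value
  structure(
    list(E0_obs = e0, n = dist$n, E0_frac_obs = e0 / dist$n,
         E0_frac_exp = expct, mean_CO = mean_CO, p_value = p,
         alternative = alternative),
    class = "assurance_test"
  )
}

#' @export
print.assurance_test <- function(x, ...) {
  cat(sprintf(
    "crossover assurance: E0 observed %d/%d (%.1f%%), Poisson expectation %.1f%%\n",
    x$E0_obs, x$n, 100 * x$E0_frac_obs, 100 * x$E0_frac_exp))
  cat(sprintf("  exact binomial p (%s): %.4g\n", x$alternative, x$p_value))
  invisible(x)
}

#' Convert total map length to mean crossovers per bivalent
#'
#' Each crossover involves two of the four chromatids, so one crossover per
#' meiosis contributes 50 cM; the mean crossover number per bivalent per
#' meiosis is `total_cM / 50`.
#'
#' @param total_cM total genetic length in cM (non-negative).
#' @return mean crossovers per bivalent per meiosis.
#' @examples
#' cM_to_mean_CO(131.6)  # 2.632
#' @export
cM_to_mean_CO <- function(total_cM) {
  if (any(!is.finite(total_cM)) || any(total_cM < 0))
    stop("`total_cM` must be non-negative", call. = FALSE)
  total_cM / 50
}

#' Purge non-exchange tetrads
#'
#' Partitions a tetrad set into the exchange subset (at least one crossover
#' on the chromosome) and the E0 (non-exchange) subset, so interference
#' statistics can be recomputed on exchange tetrads only. In strains with
#' defective crossover assurance, the E0 class is enriched for meioses in
#' which the chromosome never engaged in recombination; leaving those
#' tetrads in dilutes — and can even invert — the genetic signature of
#' interference, because they contribute PD/PD coincidences everywhere.
#'
#' @param x a [tetrad_set()].
#' @param drop_policy passed to [crossover_classes()].
#' @return list with elements `exchange` and `e0` (both `tetrad_set`),
#'   `unscorable_ids` (tetrads in neither), and `e0_fraction`.
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), n_tetrads = 500,
#'                                    assurance_fail_q = 0.15,
#'                                    obligate_CO = TRUE, seed = 1))
#' p <- purge_nonexchange(sim$tetrads)
#' n_tetrads(p$exchange); n_tetrads(p$e0)
#' @export
purge_nonexchange <- function(x, drop_policy = "any_unscorable") {
  stopifnot(inherits(x, "tetrad_set"))
  cc <- crossover_classes(x, drop_policy = drop_policy)
  co <- cc$per_tetrad
  e0_ids <- names(co)[co == 0L]
  ex_ids <- names(co)[co > 0L]
  if (length(ex_ids) == 0L)
    warning("exchange subset is empty: every scorable tetrad is E0",
            call. = FALSE)
  idx <- function(ids) match(ids, x$tetrad_id)
  list(
    exchange = x[idx(ex_ids)],
    e0 = x[idx(e0_ids)],
    unscorable_ids = setdiff(x$tetrad_id, c(e0_ids, ex_ids)),
    e0_fraction = e0_fraction(cc)
  )
}
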