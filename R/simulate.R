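#' Simulation configuration for the meiosis generator
#'
#' Full generative specification for [simulate_tetrads()]. The generator
#' models one bivalent (chromosome) per meiosis:
#'
#' * **Crossover number**: Poisson with mean `mean_CO` per bivalent
#'   (`co_model = "poisson"`), or a stationary counting-model renewal
#'   process (`co_model = "counting"`) in which crossovers are every
#'   `(m + 1)`-th event of an underlying Poisson process on the genetic
#'   scale — the standard "chi-square" interference model. `m = 0` reduces
#'   to Poisson; larger `m` spaces crossovers more evenly (positive
#'   interference).
#' * **Assurance failure**: with probability `assurance_fail_q` a meiosis is
#'   forced to zero crossovers, modelling stochastic failure of homolog
#'   engagement; `obligate_CO` redraws the remaining meioses until at least
#'   one crossover forms (zero truncation by rejection, preserving the shape
#'   above zero).
#' * **Conversion**: each marker independently undergoes gene conversion
#'   with probability `conversion_prob` per meiosis (one random chromatid's
#'   allele is flipped; no co-conversion tracts).
#' * **Nondisjunction**: an achiasmate bivalent (zero crossovers) disjoins
#'   correctly with back-up efficiency `backup_efficiency_b`; otherwise it
#'   nondisjoins at meiosis I, producing two disomic spores (BOTH at every
#'   marker) and two dead nullisomic spores.
#' * **Viability**: each remaining spore is killed independently with
#'   probability `spore_death_rate`; disomic spores are viable by default
#'   (`disome_viable`), reflecting tolerated chromosome III disomy.
#'
#' @param map a [marker_map()].
#' @param n_tetrads number of meioses to simulate.
#' @param co_model `"poisson"` or `"counting"`.
#' @param mean_CO mean crossovers per bivalent per meiosis; defaults to
#'   `total_map_length(map) / 50`.
#' @param interference_m counting-model interference parameter `m`
#'   (non-negative integer; ignored under `"poisson"`).
#' @param obligate_CO force at least one crossover in meioses not subject to
#'   assurance failure.
#' @param assurance_fail_q probability a meiosis is forced achiasmate.
#' @param conversion_prob per-marker, per-meiosis gene-conversion
#'   probability.
#' @param backup_efficiency_b probability an achiasmate bivalent still
#'   disjoins correctly at meiosis I.
#' @param spore_death_rate independent per-spore death probability.
#' @param disome_viable are disomic spores viable?
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @return an object of class `sim_config` (validated list).
#' @examples
#' cfg <- sim_config(chr3_default_map(), 1000, obligate_CO = TRUE,
#'                   interference_m = 3, seed = 42)
#' @export
sim_config <- function(map, n_tetrads,
                       co_model = c("poisson", "counting"),
                       mean_CO = total_map_length(map) / 50,
                       interference_m = 0L,
                       obligate_CO = FALSE,
                       assurance_fail_q = 0,
                       conversion_prob = 0,
                       backup_efficiency_b = 1,
                       spore_death_rate = 0,
                       disome_viable = TRUE,
                       seed = NULL) {
  stopifnot(inherits(map, "marker_map"))
  co_model <- match.arg(co_model)
  n_tetrads <- as.integer(n_tetrads)
  if (n_tetrads < 1L) stop("`n_tetrads` must be >= 1", call. = FALSE)
  probs <- c(assurance_fail_q = assurance_fail_q,
             conversion_prob = conversion_prob,
             backup_efficiency_b = backup_efficiency_b,
             spore_death_rate = spore_death_rate)
  bad <- !is.finite(probs) | probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  if (!is.finite(mean_CO) || mean_CO < 0)
    stop("`mean_CO` must be non-negative", call. = FALSE)
  interference_m <- as.integer(interference_m)
  if (interference_m < 0L)
    stop("`interference_m` must be a non-negative integer", call. = FALSE)
  if (obligate_CO && mean_CO == 0)
    stop("`obligate_CO` requires `mean_CO` > 0", call. = FALSE)
  structure(
    list(map = map, n_tetrads = n_tetrads, co_model = co_model,
         mean_CO = mean_CO, interference_m = interference_m,
         obligate_CO = isTRUE(obligate_CO),
         assurance_fail_q = assurance_fail_q,
         conversion_prob = conversion_prob,
         backup_efficiency_b = backup_efficiency_b,
         spore_death_rate = spore_death_rate,
         disome_viable = isTRUE(disome_viable),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d tetrads on %.1f cM map (%d markers), %s model\n",
    x$n_tetrads, total_map_length(x$map), length(x$map$markers), x$co_model))
  cat(sprintf(
    "  mean_CO %.3f, m %d, obligate %s, q %.3f, conv %.4f, b %.2f, death %.3f, seed %s\n",
    x$mean_CO, x$interference_m, x$obligate_CO, x$assurance_fail_q,
    x$conversion_prob, x$backup_efficiency_b, x$spore_death_rate,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Draw crossover counts and positions per meiosis under the configured
# crossover-number model (no assurance/obligate adjustments).
# Returns a list of sorted position vectors (cM from the left marker).
sample_crossover_positions <- function(config, n) {
  L <- total_map_length(config$map)
  offset <- config$map$positions_cM[1]
  lam <- config$mean_CO
  if (config$co_model == "poisson" || config$interference_m == 0L) {
    N <- stats::rpois(n, lam)
    if (config$obligate_CO) {
      z <- which(N == 0L)
      while (length(z)) {
        N[z] <- stats::rpois(length(z), lam)
        z <- z[N[z] == 0L]
      }
    }
    pos <- lapply(N, function(k) sort(stats::runif(k, 0, L)) + offset)
    return(pos)
  }
  m1 <- config$interference_m + 1L
  draw_one <- function() {
    k <- stats::rpois(1L, lam * m1)
    ev <- sort(stats::runif(k, 0, L))
    u <- sample.int(m1, 1L)              # random phase -> stationary process
    if (k < u) return(numeric(0))
    ev[seq.int(u, k, by = m1)] + offset
  }
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- draw_one()
    if (config$obligate_CO) while (length(p) == 0L) p <- draw_one()
    pos[[i]] <- p
  }
  pos
}

#' Simulate tetrads
#'
#' Forward simulation of tetrads under a [sim_config()]. For each meiosis
#' the generator (1) forces zero crossovers with probability
#' `assurance_fail_q`, otherwise draws crossover positions from the
#' configured crossover-number model (redrawing until at least one under
#' `obligate_CO`); (2) for each crossover, in left-to-right order, picks one
#' chromatid of each homolog uniformly and independently (no chromatid
#' interference) and exchanges all marker alleles distal to the crossover;
#' (3) applies per-marker gene conversion; (4) lets achiasmate bivalents
#' nondisjoin at meiosis I with probability `1 - backup_efficiency_b`;
#' (5) kills spores at `spore_death_rate`; and (6) shuffles the four spores.
#' Identical config and seed give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_result`: list with `tetrads` (a
#'   [tetrad_set()]) and `truth`, the complete per-meiosis event record
#'   (crossover count/positions/chromatid choices, conversions,
#'   nondisjunction, death draws, spore permutation). Genotypes are derived
#'   from `truth` by the deterministic replay [tetrads_from_truth()], so the
#'   two are consistent by construction.
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), 200, seed = 7))
#' sim$tetrads
#' @export
simulate_tetrads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_tetrads
  map <- config$map
  m <- length(map$markers)

  forced <- stats::runif(n) < config$assurance_fail_q
  positions <- sample_crossover_positions(config, n)
  positions[forced] <- list(numeric(0))
  n_co <- lengths(positions)

  # chromatid choices, sweeping crossovers left to right: each crossover
  # joins one strand of each homolog, where homolog identity is the strand's
  # local DNA parentage at that position (a prior crossover changes which
  # strands are sisters distal to it). Choices are uniform and independent:
  # no chromatid interference.
  chrom_a <- vector("list", n)
  chrom_b <- vector("list", n)
  for (i in which(n_co > 0L)) {
    par <- c(1L, 1L, 2L, 2L)
    xs <- positions[[i]]
    a <- integer(length(xs)); b <- integer(length(xs))
    for (k in seq_along(xs)) {
      h1 <- which(par == 1L); h2 <- which(par == 2L)
      a[k] <- h1[sample.int(2L, 1L)]
      b[k] <- h2[sample.int(2L, 1L)]
      par[c(a[k], b[k])] <- par[c(b[k], a[k])]  # distal parentage exchanged
    }
    chrom_a[[i]] <- a; chrom_b[[i]] <- b
  }
  empty <- which(n_co == 0L)
  chrom_a[empty] <- list(integer(0))
  chrom_b[empty] <- list(integer(0))

  hits <- which(matrix(stats::runif(n * m) < config$conversion_prob, n, m),
                arr.ind = TRUE)
  conversions <- data.frame(
    tetrad = hits[, 1], marker = hits[, 2],
    chromatid = if (nrow(hits)) sample.int(4L, nrow(hits), replace = TRUE)
                else integer(0))
  conversions <- conversions[order(conversions$tetrad, conversions$marker), ,
                             drop = FALSE]
  rownames(conversions) <- NULL

  nondisjunction <- n_co == 0L &
    stats::runif(n) >= config$backup_efficiency_b
  death_draws <- matrix(stats::runif(4L * n) < config$spore_death_rate, 4L, n)
  spore_perm <- vapply(seq_len(n), function(i) sample.int(4L), integer(4))

  truth <- list(
    n_co = n_co, forced_e0 = forced, positions = positions,
    chrom_a = chrom_a, chrom_b = chrom_b, conversions = conversions,
    nondisjunction = nondisjunction, death_draws = death_draws,
    spore_perm = spore_perm
  )
  structure(list(tetrads = tetrads_from_truth(truth, config), truth = truth),
            class = "sim_result")
}

#' Rebuild genotypes from a simulation truth record
#'
#' Deterministic replay of the per-meiosis event record produced by
#' [simulate_tetrads()]. The simulator itself emits its genotype table
#' through this function, so replaying a truth record reproduces the emitted
#' tetrads bit-exactly — the consistency invariant of the generator.
#'
#' @param truth the `truth` element of a `sim_result`.
#' @param config the [sim_config()] that produced it.
#' @return a [tetrad_set()].
#' @export
tetrads_from_truth <- function(truth, config) {
  map <- config$map
  m <- length(map$markers)
  n <- length(truth$n_co)
  pos <- map$positions_cM
  calls <- array(NA_integer_, dim = c(4L, m, n))
  viable <- matrix(TRUE, 4L, n)
  base <- matrix(rep(c(1L, 1L, 2L, 2L), m), nrow = 4L)
  conv <- truth$conversions
  conv_by_tetrad <- if (nrow(conv))
    split(conv[c("marker", "chromatid")], conv$tetrad) else list()

  for (i in seq_len(n)) {
    cm <- base
    xs <- truth$positions[[i]]
    ca <- truth$chrom_a[[i]]
    cb <- truth$chrom_b[[i]]
    for (k in seq_along(xs)) {
      distal <- pos > xs[k]
      if (any(distal)) {
        tmp <- cm[ca[k], distal]
        cm[ca[k], distal] <- cm[cb[k], distal]
        cm[cb[k], distal] <- tmp
      }
    }
    cv <- conv_by_tetrad[[as.character(i)]]
    if (!is.null(cv)) {
      for (r in seq_len(nrow(cv))) {
        j <- cv$marker[r]; s <- cv$chromatid[r]
        cm[s, j] <- if (cm[s, j] == 1L) 2L else 1L
      }
    }
    if (truth$nondisjunction[i]) {
      # MI nondisjunction: spores 1,2 disomic (both homologs), 3,4 nullisomic
      cm[1L, ] <- 3L
      cm[2L, ] <- 3L
      cm[3L, ] <- NA_integer_
      cm[4L, ] <- NA_integer_
      viable[3:4, i] <- FALSE
      if (!config$disome_viable) viable[1:2, i] <- FALSE
    }
    calls[, , i] <- cm
  }
  viable <- viable & !truth$death_draws
  # dead spores cannot be genotyped
  for (i in seq_len(n)) {
    dead <- !viable[, i]
    if (any(dead) && !truth$nondisjunction[i]) calls[dead, , i] <- NA_integer_
    if (any(dead) && truth$nondisjunction[i]) {
      # death draws can also kill disomic spores
      calls[dead, , i] <- NA_integer_
    }
    p <- truth$spore_perm[, i]
    calls[, , i] <- calls[p, , i]
    viable[, i] <- viable[p, i]
  }
  tetrad_set(calls, map, viable = viable)
}

#' True recombinant fractions of an interval
#'
#' Computes the exact PD/TT/NPD frequencies of a marker interval from the
#' simulation truth record — crossover positions and chromatid choices only,
#' bypassing gene conversion, nondisjunction, spore death and genotype
#' scoring. Used as an independent oracle for the estimators.
#'
#' @param sim a `sim_result` from [simulate_tetrads()].
#' @param config the [sim_config()] used.
#' @param interval an interval specification (see [classify_interval()]).
#' @return named numeric vector of `PD`, `TT`, `NPD` fractions (summing
#'   to 1).
#' @export
interval_recombinant_fraction <- function(sim, config, interval) {
  stopifnot(inherits(sim, "sim_result"), inherits(config, "sim_config"))
  ij <- interval_index(config$map, interval)
  pos <- config$map$positions_cM[ij]
  truth <- sim$truth
  n <- length(truth$n_co)
  counts <- c(PD = 0L, TT = 0L, NPD = 0L)
  for (i in seq_len(n)) {
    cm <- matrix(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L), nrow = 4L)
    xs <- truth$positions[[i]]
    ca <- truth$chrom_a[[i]]
    cb <- truth$chrom_b[[i]]
    for (k in seq_along(xs)) {
      distal <- pos > xs[k]
      if (any(distal)) {
        tmp <- cm[ca[k], distal]
        cm[ca[k], distal] <- cm[cb[k], distal]
        cm[cb[k], distal] <- tmp
      }
    }
    parental <- sum(cm[, 1] == cm[, 2])
    klass <- if (parental == 4L) "PD" else if (parental == 0L) "NPD" else "TT"
    counts[klass] <- counts[klass] + 1L
  }
  counts / n
}
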