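#' Read and write tetrad genotype tables
#'
#' The tetrad table is a tab-delimited text file with a header row and one
#' row per spore (four per tetrad). Grammar:
#'
#' ```
#' file      := header row+
#' header    := "tetrad_id" TAB "spore_id" TAB "viable" (TAB marker)+
#' row       := label TAB spore TAB flag (TAB call)+
#' spore     := "a" | "b" | "c" | "d"      (each exactly once per tetrad)
#' flag      := "0" | "1"
#' call      := "P" | "M" | "B" | "-"
#' ```
#'
#' Calls are parental-origin coded: `P` = P1, `M` = P2, `B` = BOTH (disomic
#' spore carrying both parental alleles), `-` = missing. Marker columns must
#' match the map's markers exactly and in order. Reading then writing a file
#' reproduces it losslessly; malformed rows are reported with their line
#' numbers.
#'
#' @param path file path.
#' @param map a [marker_map()] the table is bound to.
#' @return `read_tetrad_table()` returns a [tetrad_set()];
#'   `write_tetrad_table()` returns `path` invisibly.
#' @export
read_tetrad_table <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  need <- c("tetrad_id", "spore_id", "viable")
  if (!identical(names(df)[1:3], need))
    stop("tetrad table must start with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  mk <- names(df)[-(1:3)]
  if (!identical(mk, map$markers))
    stop("marker columns (", paste(mk, collapse = ", "),
         ") do not match the map (", paste(map$markers, collapse = ", "),
         ")", call. = FALSE)
  lineno <- seq_len(nrow(df)) + 1L
  ids <- unique(df$tetrad_id)
  counts <- table(df$tetrad_id)
  bad_n <- names(counts)[counts != 4L]
  if (length(bad_n))
    stop("tetrad(s) without exactly four spores: ",
         paste(bad_n, collapse = ", "), call. = FALSE)
  for (id in ids) {
    sp <- df$spore_id[df$tetrad_id == id]
    if (!setequal(sp, c("a", "b", "c", "d")) || anyDuplicated(sp))
      stop("tetrad ", id, ": spore ids must be a,b,c,d exactly once (lines ",
           paste(lineno[df$tetrad_id == id], collapse = ","), ")",
           call. = FALSE)
  }
  if (!all(df$viable %in% c("0", "1"))) {
    bad <- lineno[!df$viable %in% c("0", "1")]
    stop("invalid viability flag on line(s) ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  code <- c(P = 1L, M = 2L, B = 3L)
  for (j in mk) {
    ok <- df[[j]] %in% c("P", "M", "B", "-")
    if (!all(ok))
      stop("unknown allele code '", df[[j]][!ok][1], "' in column ", j,
           " on line ", lineno[!ok][1], call. = FALSE)
  }
  # order spores a-d within tetrads, tetrads in first-appearance order
  df <- df[order(match(df$tetrad_id, ids), df$spore_id), , drop = FALSE]
  n <- length(ids)
  m <- length(mk)
  callmat <- as.matrix(df[, mk, drop = FALSE])
  # rows are tetrad-major, spore-minor: fill (spore, tetrad, marker) then
  # permute to the (spore, marker, tetrad) layout of tetrad_set
  calls <- aperm(array(code[callmat], dim = c(4L, n, m)), c(1L, 3L, 2L))
  viable <- matrix(df$viable == "1", 4L, n)
  tetrad_set(calls, map, viable = viable, tetrad_id = ids)
}

#' @rdname read_tetrad_table
#' @param x a [tetrad_set()].
#' @export
write_tetrad_table <- function(x, path) {
  stopifnot(inherits(x, "tetrad_set"))
  n <- n_tetrads(x)
  m <- length(x$map$markers)
  rev_code <- c("P", "M", "B")
  flat <- matrix(NA_character_, 4L * n, m)
  for (j in seq_len(m)) {
    v <- as.vector(x$calls[, j, ])
    flat[, j] <- ifelse(is.na(v), "-", rev_code[v])
  }
  df <- data.frame(
    tetrad_id = rep(x$tetrad_id, each = 4L),
    spore_id = rep(c("a", "b", "c", "d"), n),
    viable = as.integer(as.vector(x$viable)),
    stringsAsFactors = FALSE
  )
  df[x$map$markers] <- as.data.frame(flat, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write marker maps
#'
#' Marker-map files are TSV with a leading comment line declaring the
#' chromosome and centromere position, then a header and one row per
#' marker:
#'
#' ```
#' #chromosome=<label>  centromere_cM=<number>
#' name  position_cM
#' ```
#'
#' @param path file path.
#' @return `read_marker_map()` returns a [marker_map()].
#' @export
read_marker_map <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("marker-map file must start with a '#chromosome=... ",
         "centromere_cM=...' line", call. = FALSE)
  get_field <- function(key) {
    mtch <- regmatches(first, regexec(paste0(key, "=([^\t ]+)"), first))[[1]]
    if (length(mtch) < 2L)
      stop("header line missing '", key, "='", call. = FALSE)
    mtch[2]
  }
  chrom <- get_field("chromosome")
  cen <- as.numeric(get_field("centromere_cM"))
  df <- utils::read.delim(path, skip = 1L, header = TRUE)
  if (!all(c("name", "position_cM") %in% names(df)))
    stop("marker-map table needs columns name, position_cM", call. = FALSE)
  marker_map(df$name, df$position_cM, chromosome = chrom, centromere_cM = cen)
}

#' @rdname read_marker_map
#' @param map a [marker_map()].
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chromosome=%s\tcentromere_cM=%s",
                     map$chromosome, format(map$centromere_cM)), con)
  utils::write.table(
    data.frame(name = map$markers, position_cM = map$positions_cM),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band-quantitation table
#'
#' TSV with columns `species` and `percent_signal` (signal per molecular
#' species as percent of total lane signal, or any common non-negative
#' unit). Returns a named numeric vector.
#'
#' @param path file path.
#' @return named numeric vector of signals.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  if (!all(c("species", "percent_signal") %in% names(df)))
    stop("quant table needs columns species, percent_signal", call. = FALSE)
  v <- as.numeric(df$percent_signal)
  if (any(!is.finite(v)) || any(v < 0))
    stop("signals must be non-negative numbers", call. = FALSE)
  stats::setNames(v, df$species)
}

#' Read and write simulation configs
#'
#' Plain-text `key = value` format, one pair per line; `#` starts a comment.
#' Recognised keys are the arguments of [sim_config()] (excluding the map,
#' supplied separately or via `map_file`).
#'
#' @param path file path.
#' @param map a [marker_map()]; overrides any `map_file` key.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path, map = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (is.null(map)) {
    map <- if ("map_file" %in% names(vals))
      read_marker_map(file.path(dirname(path), vals[["map_file"]]))
    else chr3_default_map()
  }
  num <- function(key, default) if (key %in% names(vals))
    as.numeric(vals[[key]]) else default
  lgl <- function(key, default) if (key %in% names(vals))
    toupper(vals[[key]]) %in% c("TRUE", "1", "YES") else default
  sim_config(
    map = map,
    n_tetrads = num("n_tetrads", 1000),
    co_model = if ("co_model" %in% names(vals)) vals[["co_model"]]
               else "poisson",
    mean_CO = num("mean_CO", total_map_length(map) / 50),
    interference_m = num("interference_m", 0),
    obligate_CO = lgl("obligate_CO", FALSE),
    assurance_fail_q = num("assurance_fail_q", 0),
    conversion_prob = num("conversion_prob", 0),
    backup_efficiency_b = num("backup_efficiency_b", 1),
    spore_death_rate = num("spore_death_rate", 0),
    disome_viable = lgl("disome_viable", TRUE),
    seed = if ("seed" %in% names(vals)) as.integer(vals[["seed"]]) else NULL
  )
}

#' Run the full tetrad-analysis pipeline
#'
#' Orchestrates the whole-chromosome analysis on one strain's tetrads:
#' interval tallies and Perkins map distances; NPD-ratio interference per
#' interval; adjacent-interval interference for every adjacent interval
#' pair, on all tetrads and on the E0-purged (exchange-only) subset;
#' crossover-class distribution with the Poisson assurance test; and the
#' phenotype block (viability, disomes, conversions). Deterministic given
#' the input tetrads and `seed` (which governs the permutation tests).
#'
#' @param x a [tetrad_set()].
#' @param cen_markers centromere-linked marker(s) for disome scoring
#'   (`NULL` skips it).
#' @param purge_e0 also compute interference statistics on the exchange
#'   subset.
#' @param n_perm permutations for adjacent-interval significance (0 skips).
#' @param seed RNG seed for the permutation tests.
#' @param filter_policy tetrad filter for map distances (see
#'   [tally_intervals()]).
#' @return object of class `analysis_report`: list of data.frames
#'   `map_distances`, `npd`, `adjacent`, `adjacent_purged`, `eclass`,
#'   `assurance`, `viability`, `disomes`, `conversions`, plus `provenance`
#'   (seed, settings, input hash, package version).
#' @examples
#' sim <- simulate_tetrads(sim_config(chr3_default_map(), 300, seed = 3))
#' rep <- run_pipeline(sim$tetrads, cen_markers = "CEN3", n_perm = 0)
#' rep$map_distances
#' @export
run_pipeline <- function(x, cen_markers = NULL, purge_e0 = TRUE,
                         n_perm = 1000, seed = 1,
                         filter_policy = "paper") {
  stopifnot(inherits(x, "tetrad_set"))
  if (n_tetrads(x) < 1L) stop("empty tetrad set", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(seed)
  tally <- stage("tally", tally_intervals(x, filter_policy = filter_policy))
  mapd <- stage("map", perkins_cM(tally))
  npd <- stage("npd_ratio", npd_ratio(tally))
  cc <- stage("crossover_classes", crossover_classes(x))
  total_cM <- sum(mapd$cM)
  assur <- stage("assurance",
                 assurance_test(cc, mean_CO = cM_to_mean_CO(total_cM)))
  adj_all <- stage("adjacent", adjacent_table(x, n_perm = n_perm))
  adj_purged <- NULL
  if (purge_e0) {
    purged <- stage("purge", purge_nonexchange(x))
    if (n_tetrads(purged$exchange) > 0L)
      adj_purged <- stage("adjacent_purged",
                          adjacent_table(purged$exchange, n_perm = n_perm))
  }
  viab <- stage("viability", viability_distribution(x))
  dis <- if (!is.null(cen_markers))
    stage("disomes", score_disomes(x, cen_markers)) else NULL
  conv <- stage("conversions", conversion_crosstab(x))
  structure(
    list(
      map_distances = mapd,
      npd = npd,
      adjacent = adj_all,
      adjacent_purged = adj_purged,
      eclass = data.frame(class = names(cc$counts),
                          count = as.integer(cc$counts),
                          fraction = as.integer(cc$counts) / cc$n),
      assurance = data.frame(E0_obs = assur$E0_obs, n = assur$n,
                             E0_frac_obs = assur$E0_frac_obs,
                             E0_frac_exp = assur$E0_frac_exp,
                             mean_CO = assur$mean_CO,
                             p_value = assur$p_value),
      viability = data.frame(class = names(viab$counts),
                             count = as.integer(viab$counts)),
      viability_pct = viab$viability_pct,
      total_cM = total_cM,
      disomes = dis,
      conversions = conv,
      provenance = list(seed = seed, n_perm = n_perm,
                        filter_policy = filter_policy,
                        n_tetrads = n_tetrads(x),
                        input_md5 = tetrad_md5(x),
                        package_version =
                          as.character(utils::packageVersion("tetradkit")))
    ),
    class = "analysis_report"
  )
}

# md5 of the canonical TSV serialisation of a tetrad set
tetrad_md5 <- function(x) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_tetrad_table(x, tf)
  unname(tools::md5sum(tf))
}

# adjacent-interval interference for every adjacent interval pair
adjacent_table <- function(x, n_perm = 1000) {
  iv <- interval_names(x$map)
  k <- length(iv) - 1L
  out <- vector("list", k)
  for (i in seq_len(k)) {
    a <- adjacent_interference(x, i, i + 1L, n_perm = n_perm)
    out[[i]] <- data.frame(
      ref_interval = a$ref_interval, test_interval = a$test_interval,
      adj_ratio = a$adj_ratio, ratio_fwd = a$ratio_fwd,
      ratio_rev = a$ratio_rev, p_value = a$p_value, p_chisq = a$p_chisq,
      n_AdjCO = unname(a$subset_sizes["AdjCO"]),
      n_AdjPD = unname(a$subset_sizes["AdjPD"]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("tetradkit analysis report\n")
  cat(sprintf("  tetrads: %d; spore viability %.1f%%; total map %.1f cM\n",
              x$provenance$n_tetrads, x$viability_pct, x$total_cM))
  cat(sprintf("  E0: %d/%d (%.1f%%) vs Poisson %.1f%% (p = %.3g)\n",
              x$assurance$E0_obs, x$assurance$n,
              100 * x$assurance$E0_frac_obs, 100 * x$assurance$E0_frac_exp,
              x$assurance$p_value))
  cat(sprintf("  mean adjacent-interval ratio: %.3f%s\n",
              mean(x$adjacent$adj_ratio, na.rm = TRUE),
              if (!is.null(x$adjacent_purged))
                sprintf(" (purged: %.3f)",
                        mean(x$adjacent_purged$adj_ratio, na.rm = TRUE))
              else ""))
  invisible(x)
}

#' Write an analysis report as a TSV bundle
#'
#' One TSV per report table plus a human-readable `summary.txt`, all under
#' `dir`. Numeric values are written at full precision; the summary rounds
#' cM to one decimal and percentages to match conventional reporting.
#' Regenerating the report from the same inputs and provenance (seed,
#' settings) reproduces the files byte-identically.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(as.data.frame(df), file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(report$map_distances, "map_distances")
  wr(report$npd, "npd_ratios")
  wr(report$adjacent, "adjacent_interference")
  wr(report$adjacent_purged, "adjacent_interference_purged")
  wr(report$eclass, "crossover_classes")
  wr(report$assurance, "assurance")
  wr(report$viability, "viability")
  if (!is.null(report$disomes)) wr(report$disomes$records, "disome_records")
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  p <- report$provenance
  writeLines(c(
    "tetradkit analysis report",
    sprintf("package version: %s; seed: %s; n_perm: %d; filter: %s",
            p$package_version, p$seed, p$n_perm, p$filter_policy),
    sprintf("input: %d tetrads (md5 %s)", p$n_tetrads, p$input_md5),
    sprintf("total map length: %.1f cM (%.1f crossovers per meiosis)",
            report$total_cM, cM_to_mean_CO(report$total_cM)),
    sprintf("spore viability: %.1f%%", report$viability_pct),
    sprintf("E0 tetrads: %d/%d (%.1f%%); Poisson expectation %.1f%% (p = %.3g)",
            report$assurance$E0_obs, report$assurance$n,
            100 * report$assurance$E0_frac_obs,
            100 * report$assurance$E0_frac_exp, report$assurance$p_value),
    if (!is.null(report$disomes))
      sprintf("disomic tetrads: %d/%d (%.2f%%)", report$disomes$n_flagged,
              report$disomes$n_genotypable, 100 * report$disomes$fraction)
    else "disome scoring: skipped",
    sprintf("conversion fraction: %.2f%% overall (E0: %.2f%%; Fisher p = %.3g)",
            100 * report$conversions$fractions["overall"],
            100 * report$conversions$fractions["E0"],
            report$conversions$p_value)
  ), con)
  invisible(dir)
}
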