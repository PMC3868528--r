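# Fixture builders shared across test files. All fixtures are constructed in
# code; no data files.

# Evenly spaced map with markers A, B, C, ... (10 cM apart by default).
simple_map <- function(n_markers = 3, spacing = 10, cen = 0) {
  marker_map(LETTERS[seq_len(n_markers)],
             seq(0, by = spacing, length.out = n_markers),
             chromosome = "test",
             centromere_cM = cen)
}

# Build a tetrad_set from a list of 4 x n_markers call matrices
# (1 = P1, 2 = P2, 3 = BOTH, NA = missing).
ts_from_calls <- function(call_list, map, viable = NULL) {
  n <- length(call_list)
  m <- length(map$markers)
  calls <- array(NA_integer_, dim = c(4L, m, n))
  for (i in seq_len(n)) calls[, , i] <- call_list[[i]]
  tetrad_set(calls, map, viable = viable)
}

# Canonical single-interval tetrad genotypes over a 2-marker map:
# spore rows give (marker1, marker2) origins.
calls_PD <- function() matrix(c(1, 1, 2, 2,   1, 1, 2, 2), nrow = 4)
calls_NPD <- function() matrix(c(1, 1, 2, 2,  2, 2, 1, 1), nrow = 4)
calls_TT <- function() matrix(c(1, 1, 2, 2,   1, 2, 1, 2), nrow = 4)

# Extend a 2-marker genotype to m markers by repeating the second column
# (all further intervals PD).
extend_calls <- function(base, m) {
  cbind(base[, 1, drop = FALSE],
        matrix(rep(base[, 2], m - 1), nrow = 4))
}

# A tetrad set of n_PD + n_TT + n_NPD tetrads over a 2-marker map.
ts_counts <- function(n_PD = 0, n_TT = 0, n_NPD = 0, map = simple_map(2)) {
  ts_from_calls(c(replicate(n_PD, calls_PD(), simplify = FALSE),
                  replicate(n_TT, calls_TT(), simplify = FALSE),
                  replicate(n_NPD, calls_NPD(), simplify = FALSE)),
                map)
}

# Independent brute-force two-point classifier used as an oracle: straight
# transcription of the definitions, no shared code with the package.
brute_classify <- function(calls4x2) {
  a <- calls4x2[, 1]; b <- calls4x2[, 2]
  if (any(is.na(c(a, b))) || any(c(a, b) == 3)) return("UNSCORABLE")
  if (sum(a == 1) != 2 || sum(b == 1) != 2) return("UNSCORABLE")
  par <- sum(a == b)
  if (par == 4) "PD" else if (par == 0) "NPD" else "TT"
}
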