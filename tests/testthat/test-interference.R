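# Hand-buildable two-interval genotypes over a 3-marker map: columns are
# marker origins per spore chosen so interval A-B and B-C take the given
# classes independently.
two_interval_calls <- function(ab, bc) {
  col1 <- c(1L, 1L, 2L, 2L)
  col2 <- switch(ab,
                 PD = col1,
                 TT = c(1L, 2L, 1L, 2L),
                 NPD = c(2L, 2L, 1L, 1L))
  col3 <- switch(bc,
                 PD = col2,
                 NPD = 3L - col2,
                 TT = {
                   # exchange distal alleles of one spore of each origin
                   v <- col2
                   i <- which(col2 == 1L)[1]
                   j <- which(col2 == 2L)[1]
                   v[c(i, j)] <- v[c(j, i)]
                   v
                 })
  matrix(c(col1, col2, col3), nrow = 4)
}

test_that("adjacent-interval ratio matches an exhaustive hand tally", {
  mm <- simple_map(3)
  # 12 tetrads: joint (A-B, B-C) classes chosen by hand
  spec <- list(
    c("PD", "PD"), c("PD", "PD"), c("PD", "TT"), c("PD", "TT"),
    c("PD", "TT"), c("PD", "NPD"), c("TT", "PD"), c("TT", "PD"),
    c("TT", "PD"), c("TT", "TT"), c("NPD", "PD"), c("NPD", "TT")
  )
  ts <- ts_from_calls(lapply(spec, function(s)
    two_interval_calls(s[1], s[2])), mm)
  # verify construction before using it
  expect_equal(classify_interval(ts, "A-B"),
               vapply(spec, `[`, "", 1))
  expect_equal(classify_interval(ts, "B-C"),
               vapply(spec, `[`, "", 2))

  res <- adjacent_interference(ts, "A-B", "B-C", n_perm = 0)
  # forward: AdjCO = {TT,TT,TT,TT(TT),NPD,NPD(TT)} in A-B -> 6 tetrads,
  # their B-C classes: PD,PD,PD,TT,PD,TT -> perkins = 100*(2)/(2*6)
  d_co <- 100 * (6 * 0 + 2) / (2 * 6)
  # AdjPD = 6 PD-in-A-B tetrads, B-C classes: PD,PD,TT,TT,TT,NPD
  d_pd <- 100 * (6 * 1 + 3) / (2 * 6)
  # reverse: AdjCO in B-C = {TT x5, NPD x2}... recompute by hand:
  bc <- vapply(spec, `[`, "", 2)
  ab <- vapply(spec, `[`, "", 1)
  co <- bc != "PD"
  d_co_rev <- 100 * (6 * sum(ab[co] == "NPD") + sum(ab[co] == "TT")) /
    (2 * sum(co))
  d_pd_rev <- 100 * (6 * sum(ab[!co] == "NPD") + sum(ab[!co] == "TT")) /
    (2 * sum(!co))
  expect_equal(res$ratio_fwd, d_co / d_pd)
  expect_equal(res$ratio_rev, d_co_rev / d_pd_rev)
  expect_equal(res$adj_ratio, mean(c(d_co / d_pd, d_co_rev / d_pd_rev)))
  expect_equal(unname(res$subset_sizes), c(6L, 6L))
})

test_that("complete interference gives ratio 0, independence gives ~1", {
  mm <- simple_map(3)
  # no tetrad has crossovers in both intervals
  spec <- c(replicate(6, c("TT", "PD"), simplify = FALSE),
            replicate(6, c("PD", "TT"), simplify = FALSE),
            replicate(8, c("PD", "PD"), simplify = FALSE))
  ts <- ts_from_calls(lapply(spec, function(s)
    two_interval_calls(s[1], s[2])), mm)
  res <- adjacent_interference(ts, "A-B", "B-C", n_perm = 0)
  expect_equal(res$adj_ratio, 0)

  # independent intervals: Poisson crossovers, no interference
  cfg <- sim_config(chr3_default_map(), 20000, co_model = "poisson",
                    seed = 17)
  sim <- simulate_tetrads(cfg)
  res_ind <- adjacent_interference(sim$tetrads, "CEN3-MAT", "MAT-THR4",
                                   n_perm = 0)
  expect_lt(abs(res_ind$adj_ratio - 1), 0.1)
})

test_that("permutation test detects simulated interference", {
  cfg <- sim_config(chr3_default_map(), 3000, co_model = "counting",
                    interference_m = 4, obligate_CO = TRUE, seed = 23)
  sim <- simulate_tetrads(cfg)
  res <- adjacent_interference(sim$tetrads, "CEN3-MAT", "MAT-THR4",
                               n_perm = 400)
  expect_lt(res$adj_ratio, 1)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$p_chisq, 0.05)

  # under independence the permutation p is not extreme
  cfg0 <- sim_config(chr3_default_map(), 3000, co_model = "poisson",
                     seed = 24)
  sim0 <- simulate_tetrads(cfg0)
  res0 <- adjacent_interference(sim0$tetrads, "CEN3-MAT", "MAT-THR4",
                                n_perm = 400)
  expect_gt(res0$p_value, 0.01)
})

test_that("empty subsets and zero denominators are flagged undefined", {
  mm <- simple_map(3)
  # every tetrad has a crossover in A-B: AdjPD subset is empty
  ts <- ts_from_calls(replicate(5, two_interval_calls("TT", "PD"),
                                simplify = FALSE), mm)
  res <- adjacent_interference(ts, "A-B", "B-C", n_perm = 0)
  expect_true(res$undefined)
})
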