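test_that("Perkins distances match hand evaluation of the formula", {
  expect_equal(perkins_cM(interval_tally(100, 0, 0))$cM, 0)
  expect_equal(perkins_cM(interval_tally(0, 0, 100))$cM, 50)
  expect_equal(perkins_cM(interval_tally(70, 2, 28))$cM, 20)
  expect_error(perkins_cM(interval_tally(0, 0, 0)), ">= 1")
})

test_that("Perkins estimate is zero iff no recombinant classes observed", {
  set.seed(1)
  for (i in 1:20) {
    tl <- interval_tally(sample(0:50, 1), sample(0:3, 1), sample(0:50, 1))
    if (tl$n == 0) next
    est <- perkins_cM(tl)
    expect_equal(est$cM == 0, tl$NPD == 0 && tl$TT == 0)
  }
})

test_that("Perkins is invariant under scaling all counts", {
  base <- perkins_cM(interval_tally(70, 2, 28))
  scaled <- perkins_cM(interval_tally(70 * 7, 2 * 7, 28 * 7))
  expect_equal(scaled$cM, base$cM)
  # SE shrinks by sqrt(scale)
  expect_equal(scaled$se_cM, base$se_cM / sqrt(7))
})

test_that("the two printed forms of the Perkins formula agree", {
  # (T + 3*NPD) / total * 100 versus 100*(6*NPD + TT) / (2*(PD+NPD+TT))
  set.seed(2)
  for (i in 1:25) {
    PD <- sample(0:200, 1); NPD <- sample(0:10, 1); TT <- sample(0:100, 1)
    n <- PD + NPD + TT
    if (n == 0) next
    caption_form <- (TT / 2 + 3 * NPD) / n * 100
    expect_equal(perkins_cM(interval_tally(PD, NPD, TT))$cM, caption_form)
  }
})

test_that("delta-method SE agrees with a multinomial bootstrap", {
  tl <- interval_tally(PD = 350, NPD = 10, TT = 140)
  est <- perkins_cM(tl)
  set.seed(99)
  reps <- stats::rmultinom(10000, tl$n, c(tl$PD, tl$NPD, tl$TT) / tl$n)
  boot_cM <- 100 * (6 * reps[2, ] + reps[3, ]) / (2 * tl$n)
  expect_lt(abs(stats::sd(boot_cM) - est$se_cM) / est$se_cM, 0.05)
})

test_that("Papazian expectation matches boundary and hand values", {
  expect_equal(papazian_expected_npd(0), 0)
  expect_equal(papazian_expected_npd(2 / 3), 1 / 6)
  expect_equal(papazian_expected_npd(0.4), 0.5 * (0.6 - 0.4^(2 / 3)),
               tolerance = 1e-12)
  expect_true(all(papazian_expected_npd(seq(0, 2 / 3, by = 0.01)) >= 0))
  expect_warning(out <- papazian_expected_npd(0.8), "outside")
  expect_true(is.na(out))
})

test_that("NPD ratio divides observed by Papazian-expected frequency", {
  res <- npd_ratio(interval_tally(70, 2, 28))
  expect_equal(res$fT, 0.28)
  expect_equal(res$npd_ratio, (2 / 100) / papazian_expected_npd(0.28),
               tolerance = 1e-12)
  expect_equal(round(res$npd_ratio, 2), 1.63)  # negative-interference case
  # no NPDs observed -> ratio 0
  expect_equal(npd_ratio(interval_tally(80, 0, 20))$npd_ratio, 0)
  # expected 0 (no tetratypes) with observed NPDs -> flagged infinite
  expect_equal(npd_ratio(interval_tally(98, 2, 0))$npd_ratio, Inf)
  # ratio is exactly 1 when the observed count equals the expectation
  n <- 1000; TT <- 280
  exp_npd <- papazian_expected_npd(TT / n) * n
  res1 <- npd_ratio(interval_tally(n - TT - round(exp_npd), round(exp_npd), TT))
  expect_equal(res1$npd_ratio, round(exp_npd) / exp_npd, tolerance = 1e-12)
})

test_that("NPD-ratio p-value is the exact binomial tail", {
  tl <- interval_tally(70, 2, 28)
  res <- npd_ratio(tl)
  expct <- papazian_expected_npd(0.28)
  expect_equal(res$p_value,
               stats::binom.test(2, 100, expct, alternative = "less")$p.value)
})

test_that("map length converts to mean crossover number at 50 cM per CO", {
  expect_equal(cM_to_mean_CO(131.6), 2.632)
  expect_equal(cM_to_mean_CO(116.8), 2.336)
  expect_equal(cM_to_mean_CO(0), 0)
  expect_error(cM_to_mean_CO(-1), "non-negative")
})

test_that("crossover classes follow the minimal-crossover convention", {
  mm <- simple_map(3)
  e0 <- extend_calls(calls_PD(), 3)
  e1 <- extend_calls(calls_TT(), 3)               # TT in A-B only
  e2 <- extend_calls(calls_NPD(), 3)              # NPD in A-B only
  ts <- ts_from_calls(list(e0, e1, e2), mm)
  cc <- crossover_classes(ts)
  expect_equal(unname(cc$counts[c("E0", "E1", "E2")]), c(1L, 1L, 1L))
  expect_equal(cc$mean_CO, 1)
  expect_equal(e0_fraction(cc), 1 / 3)
})

test_that("assurance test compares E0 to the Poisson zero class", {
  d <- crossover_class_counts(c(E0 = 100, E1 = 0))
  expect_equal(assurance_test(d, mean_CO = 0)$E0_frac_exp, 1)
  expect_equal(assurance_test(d, mean_CO = 2.336)$E0_frac_exp,
               exp(-2.336))
  expect_equal(round(100 * exp(-2.336)), 10)
  expect_equal(assurance_test(d, mean_CO = 2.632)$E0_frac_exp,
               exp(-2.632), tolerance = 1e-12)
  expect_equal(round(exp(-2.632), 3), 0.072)
  # p-value is the exact one-sided binomial tail in the departure direction
  d2 <- crossover_class_counts(c(E0 = 210, E1 = 600, E2 = 566))
  at <- assurance_test(d2, mean_CO = 2.336)
  expect_equal(at$alternative, "greater")
  expect_equal(at$p_value,
               stats::binom.test(210, 1376, exp(-2.336),
                                 alternative = "greater")$p.value)
})

test_that("purging partitions tetrads by exchange status", {
  mm <- simple_map(3)
  e0 <- extend_calls(calls_PD(), 3)
  e1 <- extend_calls(calls_TT(), 3)
  # no E0 tetrads: purge is the identity on the exchange subset
  ts <- ts_from_calls(replicate(5, e1, simplify = FALSE), mm)
  p <- purge_nonexchange(ts)
  expect_equal(n_tetrads(p$exchange), 5)
  expect_equal(n_tetrads(p$e0), 0)
  # only E0 tetrads: exchange subset empty, flagged
  ts0 <- ts_from_calls(replicate(4, e0, simplify = FALSE), mm)
  expect_warning(p0 <- purge_nonexchange(ts0), "empty")
  expect_equal(n_tetrads(p0$exchange), 0)
  expect_equal(p0$e0_fraction, 1)
})

test_that("purging a forced-E0 mixture recovers the exchange fraction", {
  cfg <- sim_config(chr3_default_map(), 4000, obligate_CO = TRUE,
                    assurance_fail_q = 0.15, seed = 31)
  sim <- simulate_tetrads(cfg)
  p <- purge_nonexchange(sim$tetrads)
  # purged subset has no E0 tetrads and holds ~85% of the data
  expect_equal(e0_fraction(crossover_classes(p$exchange)), 0)
  expect_lt(abs(n_tetrads(p$exchange) / 4000 - 0.85),
            3 * sqrt(0.15 * 0.85 / 4000) + 0.02)  # + slack for 2-strand doubles
})
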