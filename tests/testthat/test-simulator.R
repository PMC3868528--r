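test_that("invalid configurations error before any sampling", {
  mm <- chr3_default_map()
  expect_error(sim_config(mm, 10, assurance_fail_q = 1.2), "probabilities")
  expect_error(sim_config(mm, 10, spore_death_rate = -0.1), "probabilities")
  expect_error(sim_config(mm, 10, mean_CO = -1), "non-negative")
  expect_error(sim_config(mm, 0), ">= 1")
  expect_error(sim_config(mm, 10, mean_CO = 0, obligate_CO = TRUE),
               "obligate")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(chr3_default_map(), 300, co_model = "counting",
                    interference_m = 2, obligate_CO = TRUE,
                    conversion_prob = 0.01, spore_death_rate = 0.05,
                    assurance_fail_q = 0.1, backup_efficiency_b = 0.8,
                    seed = 123)
  s1 <- simulate_tetrads(cfg)
  s2 <- simulate_tetrads(cfg)
  expect_identical(s1$tetrads, s2$tetrads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_tetrad_table(s1$tetrads, f1)
  write_tetrad_table(s2$tetrads, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("replaying the truth record reproduces the emitted genotypes", {
  cfg <- sim_config(chr3_default_map(), 500, co_model = "counting",
                    interference_m = 3, conversion_prob = 0.02,
                    spore_death_rate = 0.1, assurance_fail_q = 0.1,
                    backup_efficiency_b = 0.7, obligate_CO = TRUE, seed = 9)
  sim <- simulate_tetrads(cfg)
  expect_identical(tetrads_from_truth(sim$truth, cfg), sim$tetrads)
})

test_that("without conversion, death or nondisjunction every marker is 2:2", {
  cfg <- sim_config(chr3_default_map(), 1000, seed = 10)
  sim <- simulate_tetrads(cfg)
  for (mk in cfg$map$markers) {
    expect_true(all(score_segregation(sim$tetrads, mk) == "2:2"))
  }
})

test_that("obligate crossover formation eliminates true E0 meioses", {
  cfg <- sim_config(chr3_default_map(), 10000, obligate_CO = TRUE, seed = 12)
  sim <- simulate_tetrads(cfg)
  expect_equal(sum(sim$truth$n_co == 0), 0L)
  # and with assurance failure, forced meioses stay achiasmate
  cfg_q <- sim_config(chr3_default_map(), 5000, obligate_CO = TRUE,
                      assurance_fail_q = 0.15, seed = 13)
  sim_q <- simulate_tetrads(cfg_q)
  expect_true(all(sim_q$truth$n_co[sim_q$truth$forced_e0] == 0))
  expect_true(all(sim_q$truth$n_co[!sim_q$truth$forced_e0] >= 1))
})

test_that("Poisson crossover counts give the analytic zero class", {
  lam <- 2.336
  cfg <- sim_config(chr3_default_map(), 50000, mean_CO = lam, seed = 14)
  sim <- simulate_tetrads(cfg)
  p0 <- exp(-lam)
  se <- sqrt(p0 * (1 - p0) / 50000)
  expect_lt(abs(mean(sim$truth$n_co == 0) - p0), 3 * se)
})

test_that("counting model with m = 0 matches the Poisson sampler", {
  mm <- chr3_default_map()
  cfg_p <- sim_config(mm, 1, co_model = "poisson")
  cfg_c <- sim_config(mm, 1, co_model = "counting", interference_m = 0)
  set.seed(15)
  n_p <- lengths(tetradkit:::sample_crossover_positions(cfg_p, 50000))
  n_c <- lengths(tetradkit:::sample_crossover_positions(cfg_c, 50000))
  ks <- suppressWarnings(stats::ks.test(n_p, n_c))
  expect_gt(ks$p.value, 0.01)
})

test_that("interference strength reduces the variance/mean ratio of N", {
  mm <- chr3_default_map()
  set.seed(16)
  vm <- vapply(c(0L, 2L, 6L), function(m) {
    cfg <- sim_config(mm, 1, co_model = "counting", interference_m = m)
    n <- lengths(tetradkit:::sample_crossover_positions(cfg, 50000))
    stats::var(n) / mean(n)
  }, 0)
  expect_true(all(diff(vm) < 0))
  expect_lt(abs(vm[1] - 1), 0.05)  # Poisson limit
})

test_that("true recombinant fractions bypass scoring and match genotypes", {
  mm <- chr3_default_map()
  # lambda = 0: all parental
  cfg0 <- sim_config(mm, 200, mean_CO = 0, seed = 18)
  f0 <- interval_recombinant_fraction(simulate_tetrads(cfg0), cfg0, "CEN3-MAT")
  expect_equal(unname(f0), c(1, 0, 0))

  # a single crossover placed in one interval makes it 100% tetratype
  truth <- list(n_co = 1L, forced_e0 = FALSE, positions = list(50),
                chrom_a = list(1L), chrom_b = list(3L),
                conversions = data.frame(tetrad = integer(0),
                                         marker = integer(0),
                                         chromatid = integer(0)),
                nondisjunction = FALSE,
                death_draws = matrix(FALSE, 4, 1),
                spore_perm = matrix(1:4, 4, 1))
  cfg1 <- sim_config(mm, 1)
  sim1 <- structure(list(tetrads = tetrads_from_truth(truth, cfg1),
                         truth = truth), class = "sim_result")
  expect_equal(unname(interval_recombinant_fraction(sim1, cfg1, "CEN3-MAT")),
               c(0, 1, 0))
  expect_equal(classify_interval(sim1$tetrads, "CEN3-MAT"), "TT")
  expect_equal(classify_interval(sim1$tetrads, "HML-CHA1"), "PD")

  # truth-based and genotype-based frequencies agree on clean simulations
  cfg <- sim_config(mm, 2000, seed = 19)
  sim <- simulate_tetrads(cfg)
  tl <- tally_intervals(sim$tetrads)
  for (iv in c("CHA1-TRP1", "CEN3-MAT")) {
    f <- interval_recombinant_fraction(sim, cfg, iv)
    row <- tl[tl$interval == iv, ]
    expect_equal(unname(f["TT"]), row$TT / row$n)
    expect_equal(unname(f["NPD"]), row$NPD / row$n)
  }
})

test_that("no-interference tetrad frequencies match the Markov closed form", {
  # With K ~ Poisson(y) crossovers in an interval and uniform chromatid
  # choice, the tetratype probability satisfies t_{k+1} = 1 - t_k/2, giving
  # fT = 2/3 (1 - exp(-3y/2)); NPD follows from npd_{k+1} = t_k/4.
  closed_form <- function(y, kmax = 60) {
    k <- 0:kmax
    pk <- stats::dpois(k, y)
    t_k <- (2 / 3) * (1 - (-1 / 2)^k)
    fT <- sum(pk * t_k)
    npd <- sum(stats::dpois(1:kmax, y) * t_k[1:kmax] / 4)
    c(TT = fT, NPD = npd)
  }
  lam <- 2.336
  mm <- chr3_default_map()
  cfg <- sim_config(mm, 50000, mean_CO = lam, seed = 20)
  sim <- simulate_tetrads(cfg)
  L <- total_map_length(mm)
  for (iv in c("TRP1-HIS4", "CEN3-MAT")) {
    f <- interval_recombinant_fraction(sim, cfg, iv)
    y <- lam * interval_lengths(mm)[[iv]] / L
    expct <- closed_form(y)
    for (klass in c("TT", "NPD")) {
      se <- sqrt(expct[[klass]] * (1 - expct[[klass]]) / 50000)
      expect_lt(abs(f[[klass]] - expct[[klass]]), 3 * se)
    }
  }
})

test_that("nondisjoined tetrads carry two viable disomes and two dead spores", {
  cfg <- sim_config(chr3_default_map(), 2000, assurance_fail_q = 0.2,
                    backup_efficiency_b = 0.5, obligate_CO = TRUE, seed = 21)
  sim <- simulate_tetrads(cfg)
  nd <- which(sim$truth$nondisjunction)
  expect_gt(length(nd), 0)
  for (i in nd[1:5]) {
    viable <- sim$tetrads$viable[, i]
    expect_equal(sum(viable), 2L)
    cc <- sim$tetrads$calls[, , i]
    expect_true(all(cc[viable, ] == 3L))
    expect_true(all(is.na(cc[!viable, ])))
  }
})
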