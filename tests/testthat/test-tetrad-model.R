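test_that("marker maps validate their invariants", {
  expect_error(marker_map("A", 0), "at least two")
  expect_error(marker_map(c("A", "B"), c(10, 5)), "increasing")
  expect_error(marker_map(c("A", "A"), c(0, 5)), "duplicate")
  expect_error(marker_map(c("A", "B"), c(0, 5), centromere_cM = 9), "span")
  mm <- simple_map(4)
  expect_equal(sum(interval_lengths(mm)), total_map_length(mm))
  expect_equal(interval_names(mm), c("A-B", "B-C", "C-D"))
})

test_that("segregation scoring counts P1:P2 patterns and flags aberrants", {
  mm <- simple_map(2)
  ts <- ts_from_calls(list(
    matrix(c(1, 1, 2, 2, 1, 1, 2, 2), nrow = 4),   # 2:2
    matrix(c(1, 1, 1, 2, 1, 1, 2, 2), nrow = 4),   # 3:1 at A
    matrix(c(1, 3, 2, NA, 1, 1, 2, 2), nrow = 4),  # BOTH + missing
    matrix(c(1, 1, 1, 1, 1, 1, 2, 2), nrow = 4)    # 4:0 at A
  ), mm)
  expect_equal(score_segregation(ts, "A"), c("2:2", "3:1", "aberrant", "4:0"))
  expect_equal(score_segregation(ts, "B"), rep("2:2", 4))
  expect_error(score_segregation(ts, "Z"), "unknown marker")
})

test_that("an inviable spore's calls are treated as missing", {
  mm <- simple_map(2)
  viable <- matrix(c(TRUE, TRUE, TRUE, FALSE), 4, 1)
  ts <- ts_from_calls(list(calls_PD()), mm, viable = viable)
  expect_equal(score_segregation(ts, "A"), "aberrant")
  expect_equal(classify_interval(ts, "A-B"), "UNSCORABLE")
})

test_that("interval classification reproduces the canonical ditype cases", {
  mm <- simple_map(2)
  ts <- ts_from_calls(list(calls_PD(), calls_NPD(), calls_TT()), mm)
  expect_equal(classify_interval(ts, c("A", "B")), c("PD", "NPD", "TT"))
  expect_error(classify_interval(ts, c("A", "A")), "distinct")
})

test_that("classification is symmetric in marker order and flags disomes", {
  mm <- simple_map(3)
  set.seed(42)
  calls <- replicate(50, matrix(sample(c(1L, 2L), 12, replace = TRUE),
                                nrow = 4), simplify = FALSE)
  ts <- ts_from_calls(calls, mm)
  expect_equal(classify_interval(ts, c("A", "C")),
               classify_interval(ts, c("C", "A")))
  # a disomic call anywhere in the pair makes the tetrad unscorable
  dis <- matrix(c(1, 3, 2, 2, 1, 1, 2, 2, 1, 1, 2, 2), nrow = 4)
  ts2 <- ts_from_calls(list(dis), mm)
  expect_equal(classify_interval(ts2, "A-B"), "UNSCORABLE")
})

test_that("two PD sub-intervals force a ditype outer interval (exhaustive)", {
  # enumerate all 4-spore configurations over 3 markers with pure P1/P2 calls
  mm <- simple_map(3)
  grid <- expand.grid(rep(list(1:2), 12))
  calls <- lapply(seq_len(nrow(grid)),
                  function(i) matrix(as.integer(grid[i, ]), nrow = 4))
  ts <- ts_from_calls(calls, mm)
  ab <- classify_interval(ts, "A-B")
  bc <- classify_interval(ts, "B-C")
  ac <- classify_interval(ts, c("A", "C"))
  sel <- ab == "PD" & bc == "PD"
  expect_gt(sum(sel), 0)
  expect_true(all(ac[sel] %in% c("PD", "NPD")))
})

test_that("interval tallies respect the filter policy and sum invariant", {
  mm <- simple_map(3)
  clean <- extend_calls(calls_TT(), 3)
  conv <- clean
  conv[4, 3] <- 1L   # 3:1 at marker C, intervals A-B/B-C unaffected at A-B
  ts <- ts_from_calls(c(replicate(5, clean, simplify = FALSE), list(conv)), mm)

  paper <- tally_intervals(ts, "paper")
  # the non-Mendelian tetrad is excluded everywhere under the paper policy
  expect_equal(paper$n, c(5L, 5L))
  expect_equal(paper$UNSCORABLE, c(1L, 1L))

  lenient <- tally_intervals(ts, "lenient")
  # under per-interval scoring it still contributes where its markers are 2:2
  expect_equal(lenient$n[lenient$interval == "A-B"], 6L)
  expect_equal(lenient$n[lenient$interval == "B-C"], 5L)

  for (tl in list(paper, lenient)) {
    expect_true(all(tl$PD + tl$NPD + tl$TT + tl$UNSCORABLE ==
                      attr(tl, "n_tetrads")))
  }
  expect_error(tally_intervals(ts_counts(1)[0]), "empty")
})

test_that("tallies of an all-PD set and a mixed set match brute force", {
  mm <- simple_map(2)
  all_pd <- ts_counts(n_PD = 10, map = mm)
  tl <- tally_intervals(all_pd)
  expect_equal(unlist(tl[1, c("PD", "NPD", "TT")]),
               c(PD = 10L, NPD = 0L, TT = 0L))

  set.seed(7)
  mixed <- replicate(6, matrix(sample(c(1L, 1L, 2L, 2L)), nrow = 4)[,
                       c(1, 1), drop = FALSE], simplify = FALSE)
  mixed <- lapply(mixed, function(m) {
    m[, 2] <- sample(m[, 2]); m
  })
  ts <- ts_from_calls(mixed, mm)
  oracle <- table(factor(vapply(mixed, brute_classify, ""),
                         levels = c("PD", "NPD", "TT", "UNSCORABLE")))
  tl <- tally_intervals(ts, "lenient")
  expect_equal(unname(tl$PD), unname(oracle[["PD"]]))
  expect_equal(unname(tl$NPD), unname(oracle[["NPD"]]))
  expect_equal(unname(tl$TT), unname(oracle[["TT"]]))
})
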