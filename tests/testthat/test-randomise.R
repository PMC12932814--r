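test_that("day-mean normalisation makes every day's mean exactly 1", {
  sc <- data.frame(day = 1, allocation = 1:2, kappa = c(2, 4))
  out <- normalise_day_mean(sc, "kappa")
  expect_equal(out$kappa, c(2 / 3, 4 / 3))
  # all equal -> all 1
  sc2 <- data.frame(day = rep(1:2, each = 3), allocation = rep(1:3, 2),
                    entropy = 5)
  expect_true(all(normalise_day_mean(sc2, "entropy")$entropy == 1))
  # two days with different means: every (variable, day) mean is 1
  sc3 <- make_sc_table(days = 1:2, seed = 4)
  sc3$kappa <- sc3$kappa + ifelse(sc3$day == 2, 10, 0)
  out3 <- normalise_day_mean(sc3)
  for (v in analysis_variables()) {
    expect_equal(as.numeric(tapply(out3[[v]], out3$day, mean)), c(1, 1))
  }
  expect_equal(mean(out3$kappa), 1)
  # zero day mean is rejected with the variable and day named
  sc4 <- data.frame(day = 1, allocation = 1:2, lend = c(-1, 1))
  expect_error(normalise_day_mean(sc4, "lend"), "lend")
})

test_that("scheme search scores partitions and is nested in n_candidates", {
  sc <- make_sc_table(seed = 8)
  # constant data: every partition scores 0
  sc0 <- sc
  for (v in analysis_variables()) sc0[[v]] <- 7
  s0 <- search_schemes(sc0, n_candidates = 50, seed = 1, normalise = FALSE)
  expect_true(all(s0$scores == 0))
  # nested sampling: first k candidates identical, so best non-increasing
  small <- search_schemes(sc, n_candidates = 200, seed = 5)
  large <- search_schemes(sc, n_candidates = 2000, seed = 5)
  expect_identical(small$permutations, large$permutations[1:200, ])
  expect_lte(min(large$scores), min(small$scores))
  # positions must exist in the layout
  sc_bad <- sc; sc_bad$allocation[1] <- 99
  expect_error(search_schemes(sc_bad, n_candidates = 5, seed = 1),
               "absent from the layout")
})

test_that("selected schemes are disjoint, minimal and pass the location check", {
  sc <- make_sc_table(seed = 12)
  search <- search_schemes(sc, n_candidates = 500, seed = 2)
  scheme <- select_scheme(search, alpha = 0.05)
  expect_s3_class(scheme, "ccc_scheme")
  pos <- unlist(scheme$blocks)
  expect_length(pos, 24L)
  expect_false(anyDuplicated(pos) > 0)
  expect_true(all(pos %in% attr(chamber_layout(), "used")))
  expect_true(all(scheme$anova_p > 0.05))
  expect_length(scheme$anova_p, 7L)
  # minimality: no candidate that passed the filter scores lower
  expect_equal(scheme$score, search$scores[search$order[scheme$rank]])
  if (scheme$rank > 1) {
    better <- search$order[seq_len(scheme$rank - 1)]
    expect_true(all(search$scores[better] <= scheme$score))
  }
  # alpha = 0 disables the filter: the top-ranked candidate is returned
  top <- select_scheme(search, alpha = 0)
  expect_equal(top$rank, 1L)
  expect_equal(top$score, min(search$scores))
})

test_that("a strong position gradient can defeat the location check", {
  # inner positions systematically high: block ANOVAs reject for any of a
  # few candidates, so selection fails loudly
  sc <- make_sc_table(seed = 3, position_effect = (1:24) * 5)
  search <- search_schemes(sc, n_candidates = 3, seed = 9)
  expect_error(select_scheme(search, alpha = 0.9999, max_check = 3),
               "no candidate scheme passed")
})

test_that("scheme JSON serialisation round-trips", {
  sc <- make_sc_table(seed = 21)
  scheme <- select_scheme(search_schemes(sc, n_candidates = 100, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_scheme_json(scheme, f)
  back <- read_scheme_json(f)
  expect_equal(back$blocks, scheme$blocks)
  expect_equal(back$score, scheme$score, tolerance = 1e-12)
  expect_equal(back$anova_p, scheme$anova_p, tolerance = 1e-12)
})

test_that("rotations are Latin squares covering every (sample, block) pair", {
  for (seed in c(1, 2, 77)) {
    rot <- build_rotation(seed = seed)
    for (i in 1:6) {
      expect_setequal(rot[i, ], 1:6)   # each day: blocks are a permutation
      expect_setequal(rot[, i], 1:6)   # each sample visits every block
    }
  }
  expect_false(identical(build_rotation(seed = 1), build_rotation(seed = 2)))
  # completeness: every (sample, block) pair occurs exactly once
  rot <- build_rotation(seed = 5)
  expect_true(all(table(col(rot), rot) == 1L))
})

test_that("null SC data fail the per-variable filter at about 1-(1-alpha)^7", {
  # one random candidate per independently drawn null dataset: each of the
  # 7 block ANOVAs then has a uniform p-value, so the candidate fails the
  # filter with probability 1 - (1 - alpha)^7
  alpha <- 0.2  # inflated so the rate is measurable with few datasets
  n_data <- 200
  fails <- vapply(seq_len(n_data), function(i) {
    sc <- make_sc_table(seed = 5000 + i)
    search <- search_schemes(sc, n_candidates = 1, seed = i, normalise = FALSE)
    tryCatch({
      select_scheme(search, alpha = alpha, max_check = 1)
      FALSE
    }, error = function(e) TRUE)
  }, logical(1))
  expected <- 1 - (1 - alpha)^7
  se <- sqrt(expected * (1 - expected) / n_data)
  expect_lt(abs(mean(fails) - expected), 3 * se + 0.02)
})
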