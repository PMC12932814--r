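test_that("correlation filter drops one of any collinear pair", {
  withr::with_seed(14, {
    n <- 200
    A <- rnorm(n)
    df <- data.frame(A = A, B = A, C = rnorm(n))
  })
  out <- correlation_filter(df, c("A", "B", "C"))
  expect_length(out$kept, 2L)
  expect_true("C" %in% out$kept)
  expect_equal(nrow(out$dropped), 1L)
  expect_equal(abs(out$dropped$r), 1, tolerance = 1e-12)
  # independent noise columns at n = 200 all survive
  withr::with_seed(15, {
    noise <- as.data.frame(matrix(rnorm(200 * 6), 200))
  })
  out2 <- correlation_filter(noise, names(noise))
  expect_length(out2$kept, 6L)
  # no kept pair exceeds the threshold, ever
  sub <- abs(out2$correlation[out2$kept, out2$kept])
  diag(sub) <- 0
  expect_lte(max(sub), 0.7)
  # constant columns are dropped with a warning
  df$K <- 1
  expect_warning(out3 <- correlation_filter(df, c("A", "B", "C", "K")),
                 "constant")
  expect_false("K" %in% out3$kept)
})

test_that("ANOVA matches a projection-matrix oracle on a small fixture", {
  withr::with_seed(5, {
    fx <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
    fx <- fx[rep(seq_len(nrow(fx)), each = 2), ]
    fx$y <- rnorm(nrow(fx)) + 2 * (fx$A == "a2") + (fx$B == "b3")
  })
  an <- fit_anova(fx, "y", c("A", "B"), ss_type = "I")
  oracle <- projection_ss(fx, "y", c("A", "B", "A:B"))
  expect_equal(an$sum_sq[an$effect == "A"], unname(oracle$ss["A"]),
               tolerance = 1e-8)
  expect_equal(an$sum_sq[an$effect == "B"], unname(oracle$ss["B"]),
               tolerance = 1e-8)
  expect_equal(an$sum_sq[an$effect == "A:B"], unname(oracle$ss["A:B"]),
               tolerance = 1e-8)
  expect_equal(an$sum_sq[an$effect == "Residuals"], oracle$resid_ss,
               tolerance = 1e-8)
  # balanced designs: Type I and Type II agree
  an2 <- fit_anova(fx, "y", c("A", "B"), ss_type = "II")
  for (e in c("A", "B", "A:B")) {
    expect_equal(an2$sum_sq[an2$effect == e], an$sum_sq[an$effect == e],
                 tolerance = 1e-8)
  }
})

test_that("a perfect effect yields the infinite-F sentinel", {
  fx <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  fx <- fx[rep(1:4, each = 3), ]
  fx$y <- as.numeric(fx$A == "a2")
  an <- fit_anova(fx, "y", c("A", "B"))
  expect_equal(an$F[an$effect == "A"], Inf)
  expect_equal(an$p[an$effect == "A"], 0)
  expect_equal(an$p[an$effect == "B"], 1)
})

test_that("aliased factors and degenerate levels are rejected", {
  fx <- data.frame(A = rep(c("x", "y"), 6), y = rnorm(12))
  fx$B <- fx$A  # perfectly confounded
  expect_error(fit_anova(fx, "y", c("A", "B")), "aliased")
  fx$C <- "only-level"
  expect_error(fit_anova(fx, "y", c("A", "C")), "fewer than 2 levels")
})

test_that("ANOVA type-I error under the null is near the nominal 0.01", {
  n_sim <- 1000
  rates <- withr::with_seed(61, {
    fx <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                      C = c("c1", "c2"), D = c("d1", "d2"))
    fx <- fx[rep(seq_len(nrow(fx)), each = 3), ]
    vapply(seq_len(n_sim), function(i) {
      fx$y <- rnorm(nrow(fx))
      an <- fit_anova(fx, "y", c("A", "B", "C", "D"))
      an$p[match(c("A", "B", "C", "D"), an$effect)] < 0.01
    }, logical(4))
  })
  se <- sqrt(0.01 * 0.99 / (4 * n_sim))
  expect_lt(abs(mean(rates) - 0.01), 3 * se)
})

test_that("protected LSD honours the protection rule and the t^2 = F identity", {
  withr::with_seed(9, {
    # each experimental unit appears once per B level with identical y,
    # so SS(B) is exactly zero and the protection rule must fire for B
    unit_y <- rnorm(12) + 3 * rep(c(0, 1), each = 6)
    fx <- data.frame(A = rep(rep(c("a1", "a2"), each = 6), 2),
                     B = rep(c("b1", "b2"), each = 12),
                     y = rep(unit_y, 2))
  })
  an <- fit_anova(fx, "y", c("A", "B"))
  lsd <- protected_lsd(an, "A", alpha = 0.01)
  expect_equal(nrow(lsd), 1L)
  # balanced two-level factor: t^2 equals the main-effect F
  expect_equal(lsd$t^2, an$F[an$effect == "A"], tolerance = 0.05)
  # non-significant factor: empty table (protection)
  lsd_b <- protected_lsd(an, "B", alpha = 0.01)
  expect_equal(nrow(lsd_b), 0L)
  expect_error(protected_lsd(an, "Z"), "not part of the fitted model")
  # three groups, one outlying mean: its comparisons have the smallest p
  withr::with_seed(10, {
    fg <- data.frame(G = rep(c("g1", "g2", "g3"), each = 10),
                     H = rep(c("h1", "h2"), 15))
    fg$y <- rnorm(30, sd = 0.5) + 5 * (fg$G == "g3")
  })
  ang <- fit_anova(fg, "y", c("G", "H"))
  lsg <- protected_lsd(ang, "G", alpha = 0.01)
  expect_equal(nrow(lsg), 3L)
  outlier_rows <- lsg$level_i == "g3" | lsg$level_j == "g3"
  expect_lt(max(lsg$p[outlier_rows]), min(lsg$p[!outlier_rows]))
})

test_that("Cohen's d matches hand calculation and its invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(1.2, 3.4, 2.2, 5.5); b <- c(0.3, 1.1, 2.0)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(2 * a + 5, 2 * b + 5), cohens_d(a, b))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
  expect_equal(as.character(effect_magnitude(c(0.1, 0.3, 0.6, 1.9))),
               c("negligible", "small", "medium", "large"))
})

test_that("significance stars follow the reporting thresholds", {
  expect_equal(format_stars(c(0.5, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***"))
})

test_that("sensitivity tests recover a planted subspecies effect", {
  d <- build_verum_design()
  ft <- generate_feature_table(
    d, effect_spec(effects = list(l250 = c(subspecies = 1.5)), seed = 44))
  res <- run_sensitivity_test(ft, d, "subspecies")
  row <- res[res$variable == "l250", ]
  expect_lt(row$p_value, 0.01)
  expect_equal(row$interactions, "-")
  expect_equal(row$effect_size, 1.5, tolerance = 0.35)
  # the contrast's LSD table exists only for significant variables
  lsd <- attr(res, "lsd")
  expect_gt(nrow(lsd$l250), 0)
  for (v in res$variable[res$p_value >= 0.01]) {
    expect_equal(nrow(lsd[[v]]), 0L)
  }
  # the deciduous test analyses exactly the 192-plate subset
  res2 <- run_sensitivity_test(ft, d, "deciduous")
  expect_equal(attr(res2, "n"), 192L)
})

test_that("single-level nuisance factors are dropped from reduced designs", {
  d1 <- build_verum_design(n_days = 1)
  ft <- generate_feature_table(d1, effect_spec(seed = 77))
  expect_warning(res <- run_sensitivity_test(ft, d1, "subspecies"),
                 "single-level factor")
  expect_equal(attr(res, "n"), 48L)
  expect_equal(nrow(res), 7L)
})

test_that("day-interaction flags trigger the per-day drill-down", {
  d <- build_verum_design()
  # effect present only on days 1-3: a genuine day x subspecies interaction
  spec <- effect_spec(seed = 52)
  ft <- generate_feature_table(d, spec)
  sgn <- ifelse(d$subspecies == "VAA", 0.5, -0.5)
  ft$kappa <- ft$kappa + 1.6 * sgn * (d$day <= 3)
  res <- run_sensitivity_test(ft, d, "subspecies")
  row <- res[res$variable == "kappa", ]
  expect_true(grepl("d", row$interactions))
  drill <- attr(res, "per_day")$kappa
  expect_false(is.null(drill))
  expect_true(all(drill$significant[drill$day <= 3]))
  expect_false(any(drill$significant[drill$day > 3]))
})
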