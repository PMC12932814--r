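#' Correlation-based variable selection
#'
#' Greedy elimination on the Pearson correlation matrix: while any kept
#' pair has `|r| > threshold`, take the worst-offending pair and drop the
#' member with the larger mean `|r|` against the other kept variables.
#' Constant columns (undefined correlation) are dropped up front with a
#' warning.
#'
#' @param features Data frame holding the candidate columns.
#' @param candidates Character vector of candidate variable names.
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @return An object of class `ccc_corr_filter`: `correlation` (full
#'   matrix over the non-constant candidates), `kept`, and `dropped` (a
#'   data frame naming the `|r| > threshold` partner responsible).
#' @export
correlation_filter <- function(features, candidates, threshold = 0.7) {
  miss <- setdiff(candidates, names(features))
  if (length(miss)) stop("missing candidate column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(features) < 3L) stop("need at least 3 observations")
  X <- as.matrix(features[, candidates, drop = FALSE])
  const <- apply(X, 2L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  dropped <- data.frame(variable = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(candidates[const], collapse = ", "))
    dropped <- rbind(dropped, data.frame(variable = candidates[const],
                                         partner = NA_character_,
                                         r = NA_real_))
    X <- X[, !const, drop = FALSE]
  }
  R <- stats::cor(X)
  kept <- colnames(X)
  repeat {
    sub <- abs(R[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (!length(kept) || max(sub) <= threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    mean_abs <- function(v) {
      others <- setdiff(kept, v)
      if (!length(others)) 0 else mean(abs(R[v, others]))
    }
    drop_var <- if (mean_abs(a) >= mean_abs(b)) a else b
    partner <- if (drop_var == a) b else a
    dropped <- rbind(dropped, data.frame(variable = drop_var,
                                         partner = partner,
                                         r = R[drop_var, partner]))
    kept <- setdiff(kept, drop_var)
  }
  structure(list(correlation = R, kept = kept, dropped = dropped,
                 threshold = threshold),
            class = "ccc_corr_filter")
}

#' @export
print.ccc_corr_filter <- function(x, ...) {
  cat(sprintf("Correlation filter (|r| > %.2f): kept %d, dropped %d\n",
              x$threshold, length(x$kept), nrow(x$dropped)))
  invisible(x)
}

#' Fixed-effects factorial ANOVA (main effects + two-way interactions)
#'
#' Fits `response ~ (f1 + f2 + ... )^2` as a fixed-effects linear model
#' with sum-to-zero factor coding and summarises it as an F-test table.
#' Type-II sums of squares (the default) keep main-effect tests meaningful
#' in the unbalanced pooled layouts; on balanced designs they coincide
#' with sequential (Type-I) sums of squares. A saturated fit with zero
#' residual variance reports `F = Inf`, `p = 0` for effects carrying sum
#' of squares.
#'
#' @param data Data frame containing the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (each must have
#'   >= 2 levels in `data`).
#' @param ss_type `"II"` (default) or `"I"`.
#' @param interactions Include all two-way interactions (default `TRUE`).
#' @return An object of class `ccc_anova`: a data frame with columns
#'   `effect`, `df`, `sum_sq`, `mean_sq`, `F`, `p` (including the
#'   residual row), carrying the fitted model and inputs as attributes.
#' @export
fit_anova <- function(data, response, factors, ss_type = c("II", "I"),
                      interactions = TRUE) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.data.frame(data), response %in% names(data))
  miss <- setdiff(factors, names(data))
  if (length(miss)) stop("missing factor column(s): ",
                         paste(miss, collapse = ", "))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels in the data")
    }
  }
  rhs <- if (interactions && length(factors) > 1L) {
    paste0("(", paste(factors, collapse = " + "), ")^2")
  } else {
    paste(factors, collapse = " + ")
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = ctr)
  if (any(is.na(stats::coef(fit)))) {
    stop("model is rank deficient: factors are aliased/confounded ",
         "(e.g. batch and chamber); exclude the aliased factor")
  }
  tab <- NULL
  if (ss_type == "II") {
    # a saturated fit (zero residual SS) breaks the Type-II computation;
    # fall back to the sequential table, on which the infinite-F sentinel
    # is applied below
    tab <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
    if (!is.null(tab)) {
      out <- data.frame(effect = rownames(tab),
                        df = tab$Df,
                        sum_sq = tab$`Sum Sq`,
                        mean_sq = tab$`Sum Sq` / tab$Df,
                        F = tab$`F value`,
                        p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
    }
  }
  if (is.null(tab)) {
    tab <- suppressWarnings(stats::anova(fit))
    out <- data.frame(effect = rownames(tab),
                      df = tab$Df, sum_sq = tab$`Sum Sq`,
                      mean_sq = tab$`Mean Sq`, F = tab$`F value`,
                      p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  }
  res <- out$effect == "Residuals"
  tot_ss <- sum(out$sum_sq)
  if (any(res) && (out$sum_sq[res] <= 1e-10 * max(tot_ss, 1))) {
    degen <- !res & out$sum_sq > 1e-10 * max(tot_ss, 1)
    out$F[degen] <- Inf
    out$p[degen] <- 0
    out$F[!res & !degen] <- 0
    out$p[!res & !degen] <- 1
  }
  out$effect <- gsub(":", ":", out$effect, fixed = TRUE)
  rownames(out) <- NULL
  structure(out, class = c("ccc_anova", "data.frame"),
            model = fit, data = data, response = response,
            factors = factors, ss_type = ss_type)
}

.anova_p <- function(anova, effect) {
  i <- match(effect, anova$effect)
  if (is.na(i)) {
    # interaction terms may be stored with the factors in either order
    flip <- vapply(strsplit(anova$effect, ":", fixed = TRUE), function(x) {
      length(x) == 2L && identical(sort(x), sort(strsplit(effect, ":")[[1]]))
    }, logical(1))
    i <- which(flip)[1]
  }
  if (is.na(i) || !length(i)) stop("effect '", effect, "' not in the model")
  anova$p[i]
}

#' Protected Fisher's LSD pairwise comparisons
#'
#' Pairwise least-significant-difference t-tests for one factor,
#' performed only when that factor's preceding ANOVA F-test is significant
#' (`p < alpha`); otherwise an empty table is returned (the protection
#' rule). Each pair is compared with
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))`
#' on the model's residual degrees of freedom.
#'
#' @param anova A `ccc_anova` from [fit_anova()].
#' @param factor Name of the factor to compare.
#' @param alpha Protection threshold (default 0.01).
#' @return Data frame with columns `level_i`, `level_j`, `diff`, `se`,
#'   `t`, `df`, `p`; zero rows when protection withholds the comparisons.
#' @export
protected_lsd <- function(anova, factor, alpha = 0.01) {
  stopifnot(inherits(anova, "ccc_anova"))
  if (!factor %in% attr(anova, "factors")) {
    stop("factor '", factor, "' was not part of the fitted model")
  }
  empty <- data.frame(level_i = character(), level_j = character(),
                      diff = numeric(), se = numeric(), t = numeric(),
                      df = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (.anova_p(anova, factor) >= alpha) return(empty)
  data <- attr(anova, "data")
  y <- data[[attr(anova, "response")]]
  f <- data[[factor]]
  res <- anova[anova$effect == "Residuals", ]
  mse <- res$mean_sq
  dfr <- res$df
  lev <- levels(f)
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  rows <- list()
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      d <- means[i] - means[j]
      tt <- if (se > 0) d / se else sign(d) * Inf
      rows[[length(rows) + 1L]] <- data.frame(
        level_i = lev[i], level_j = lev[j], diff = unname(d),
        se = unname(se), t = unname(tt), df = dfr,
        p = 2 * stats::pt(-abs(tt), dfr), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohen's d (pooled-SD standardised mean difference)
#'
#' `d = (mean_a - mean_b) / s_pooled` with
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return The signed effect size `d`.
#' @seealso [effect_magnitude()] for the small/medium/large labels.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (!is.finite(sp) || sp <= 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sp
}

#' Conventional magnitude label for an effect size
#'
#' 0.2 is considered a small, 0.5 a medium and 0.8 a large effect.
#'
#' @param d Numeric effect size(s).
#' @return Character vector: `"negligible"`, `"small"`, `"medium"`,
#'   `"large"`.
#' @export
effect_magnitude <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

#' Significance stars at the evaluation's thresholds
#' @param p Numeric p-value(s).
#' @return `"***"` for p < 0.0001, `"**"` < 0.001, `"*"` < 0.01, else "".
#' @export
format_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.01] <- "*"
  out[p < 0.001] <- "**"
  out[p < 1e-4] <- "***"
  out
}

.interaction_letter <- c(day = "d", batch = "b", blending = "p",
                         host_tree = "h", subspecies = "s")

#' Run one sensitivity test over all analysis variables
#'
#' Joins the feature table to the design, applies the test's subset (see
#' [sensitivity_subset()]), and for each of the seven variables fits the
#' four-way fixed-effects ANOVA (main effects + two-way interactions),
#' reporting the main-effect p-value of the factor of interest, the raw
#' pooled Cohen's d of its two-level contrast, and which interactions
#' involving any model factor and the factor of interest reach
#' significance (coded d/b/p/h for day, batch, blending procedure and host
#' tree). When a day interaction is flagged, a per-day LSD-style
#' drill-down reports on which experimental days the contrast is
#' significant.
#'
#' @param features Feature table with `plate_id` and the variable columns.
#' @param design A `ccc_design`.
#' @param test_id `"subspecies"`, `"deciduous"` or `"blending"`.
#' @param alpha Significance threshold (default 0.01).
#' @param variables Variables to analyse; default [analysis_variables()].
#' @param ss_type Sums-of-squares type for [fit_anova()].
#' @return An object of class `ccc_sensitivity`: a data frame with one row
#'   per variable (`variable`, `p_value`, `stars`, `effect_size`,
#'   `magnitude`, `interactions`), with per-variable ANOVA tables, LSD
#'   tables and per-day drill-downs as attributes.
#' @export
run_sensitivity_test <- function(features, design,
                                 test_id = c("subspecies", "deciduous",
                                             "blending"),
                                 alpha = 0.01, variables = analysis_variables(),
                                 ss_type = "II") {
  test_id <- match.arg(test_id)
  stopifnot("plate_id" %in% names(features))
  miss <- setdiff(variables, names(features))
  if (length(miss)) stop("feature table lacks variable(s): ",
                         paste(miss, collapse = ", "))
  sub <- sensitivity_subset(design, test_id)
  dat <- merge(sub$design, features, by = "plate_id", sort = FALSE)
  if (nrow(dat) != nrow(sub$design)) {
    stop("feature table does not cover the design subset (",
         nrow(dat), " of ", nrow(sub$design), " plates matched)")
  }
  focus <- sub$focus
  if (length(unique(dat[[focus]])) < 2L) {
    stop("factor of interest '", focus, "' has a single level in the data")
  }
  single <- sub$factors[vapply(sub$factors,
                               function(f) length(unique(dat[[f]])) < 2L,
                               logical(1))]
  if (length(single)) {
    warning("dropping single-level factor(s) from the model: ",
            paste(single, collapse = ", "))
    sub$factors <- setdiff(sub$factors, single)
  }
  rows <- list(); anovas <- list(); lsds <- list(); by_day <- list()
  for (v in variables) {
    an <- fit_anova(dat, v, sub$factors, ss_type = ss_type)
    p_main <- .anova_p(an, focus)
    ga <- dat[[v]][dat[[focus]] == sub$contrast[1]]
    gb <- dat[[v]][dat[[focus]] == sub$contrast[2]]
    d <- cohens_d(ga, gb)
    partners <- setdiff(sub$factors, focus)
    flagged <- character(0)
    for (f in partners) {
      p_int <- .anova_p(an, paste(f, focus, sep = ":"))
      if (is.finite(p_int) && p_int < alpha) {
        flagged <- c(flagged, unname(.interaction_letter[f]))
      }
    }
    lsds[[v]] <- protected_lsd(an, focus, alpha = alpha)
    if ("d" %in% flagged) {
      by_day[[v]] <- .per_day_contrast(an, dat, v, focus, sub$contrast, alpha)
    }
    anovas[[v]] <- an
    rows[[v]] <- data.frame(
      variable = v, p_value = p_main, stars = format_stars(p_main),
      effect_size = d,
      magnitude = as.character(effect_magnitude(d)),
      interactions = if (length(flagged)) paste(flagged, collapse = ",") else "-",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ccc_sensitivity", "data.frame"),
            test_id = test_id, focus = focus, contrast = sub$contrast,
            alpha = alpha, n = nrow(dat), anova = anovas, lsd = lsds,
            per_day = by_day)
}

# per-day contrast drill-down using the full model's residual variance
.per_day_contrast <- function(anova, dat, v, focus, contrast, alpha) {
  res <- anova[anova$effect == "Residuals", ]
  mse <- res$mean_sq; dfr <- res$df
  days <- sort(unique(dat$day))
  rows <- lapply(days, function(dy) {
    a <- dat[[v]][dat$day == dy & dat[[focus]] == contrast[1]]
    b <- dat[[v]][dat$day == dy & dat[[focus]] == contrast[2]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tt <- (mean(a) - mean(b)) / se
    data.frame(day = dy, diff = mean(a) - mean(b), t = tt, df = dfr,
               p = 2 * stats::pt(-abs(tt), dfr))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}

#' @export
print.ccc_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity test '%s' (%s: %s vs %s), n = %d\n",
              attr(x, "test_id"), attr(x, "focus"),
              attr(x, "contrast")[1], attr(x, "contrast")[2], attr(x, "n")))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  df$effect_size <- round(df$effect_size, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity result (and its LSD tables) as CSV
#' @param result A `ccc_sensitivity`.
#' @param path Output CSV path; LSD details go to `<path>_lsd.csv` when
#'   any comparison was triggered.
#' @export
write_sensitivity_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  lsd <- attr(result, "lsd")
  lsd_rows <- do.call(rbind, lapply(names(lsd), function(v) {
    if (nrow(lsd[[v]])) cbind(variable = v, lsd[[v]]) else NULL
  }))
  if (!is.null(lsd_rows) && nrow(lsd_rows)) {
    utils::write.csv(lsd_rows, sub("\\.csv$", "_lsd.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
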