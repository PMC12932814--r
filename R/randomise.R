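#' Normalise systematic-control measurements to the day mean
#'
#' Divides every value by the mean of its (variable, day) cell, making
#' days and variables of different scales commensurable: after
#' normalisation every per-day per-variable mean equals 1.
#'
#' @param sc_table Data frame with a `day` column and the variable columns.
#' @param variables Character vector of variable columns; defaults to
#'   [analysis_variables()] intersected with the table's columns.
#' @return The table with the variable columns replaced by their
#'   day-mean-normalised values.
#' @export
normalise_day_mean <- function(sc_table, variables = NULL) {
  stopifnot(is.data.frame(sc_table), "day" %in% names(sc_table))
  if (is.null(variables)) {
    variables <- intersect(analysis_variables(), names(sc_table))
  }
  if (!length(variables)) stop("no variable columns to normalise")
  miss <- setdiff(variables, names(sc_table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (v in variables) {
    mday <- tapply(sc_table[[v]], sc_table$day, mean)
    bad <- names(mday)[!is.finite(mday) | mday == 0]
    if (length(bad)) {
      stop("zero or undefined day mean for variable '", v, "' on day(s) ",
           paste(bad, collapse = ", "))
    }
    sc_table[[v]] <- as.numeric(sc_table[[v]] / mday[as.character(sc_table$day)])
  }
  sc_table
}

# mean normalised value per used position x variable
.position_means <- function(sc_norm, used, variables) {
  M <- matrix(NA_real_, length(used), length(variables),
              dimnames = list(used, variables))
  for (v in variables) {
    pm <- tapply(sc_norm[[v]], sc_norm$allocation, mean)
    miss <- setdiff(as.character(used), names(pm))
    if (length(miss)) {
      stop("systematic-control data lack position(s) ",
           paste(miss, collapse = ", "))
    }
    M[, v] <- pm[as.character(used)]
  }
  M
}

#' Search random block-randomisation schemes on systematic-control data
#'
#' Generates `n_candidates` random partitions of the chamber's 24 used
#' positions into 6 blocks of 4 and scores each by the dispersion of the
#' block means on day-mean-normalised systematic-control data: per
#' variable, the SD of the 6 block means; aggregated over the variables by
#' their mean (or maximum). Candidates are generated sequentially from the
#' seed, so the first `k` candidates of a longer search equal a shorter
#' search with the same seed (the best score is non-increasing in
#' `n_candidates`).
#'
#' @param sc_table Systematic-control measurements: data frame with `day`,
#'   `allocation` and the variable columns.
#' @param layout A [chamber_layout()]; its used positions must be covered
#'   by `sc_table`.
#' @param n_candidates Number of random partitions to draw (the original
#'   procedure used 2,000,000).
#' @param seed Integer seed; the search is deterministic per seed.
#' @param variables Variable columns to score on.
#' @param aggregate `"mean"` (default) or `"max"` over the per-variable
#'   SDs.
#' @param normalise Apply [normalise_day_mean()] first (default `TRUE`).
#' @param chamber Chamber id recorded in the result.
#' @return An object of class `ccc_scheme_search`: candidate permutations,
#'   ascending-score order, scores, and the scoring inputs.
#' @export
search_schemes <- function(sc_table, layout = chamber_layout(),
                           n_candidates = 2e6, seed = 1L,
                           variables = NULL, aggregate = c("mean", "max"),
                           normalise = TRUE, chamber = 1L) {
  aggregate <- match.arg(aggregate)
  n_candidates <- as.integer(n_candidates)
  if (n_candidates < 1L) stop("n_candidates must be >= 1")
  used <- attr(layout, "used")
  if (length(used) != 24L) stop("layout must expose 24 used positions")
  if (is.null(variables)) {
    variables <- intersect(analysis_variables(), names(sc_table))
  }
  if (!length(variables)) stop("no variable columns found in sc_table")
  extra <- setdiff(unique(sc_table$allocation), layout$position)
  if (length(extra)) {
    stop("sc_table contains positions absent from the layout: ",
         paste(extra, collapse = ", "))
  }
  sc_norm <- if (normalise) normalise_day_mean(sc_table, variables) else sc_table
  M <- .position_means(sc_norm, used, variables)   # 24 x V
  block_of <- rep(1:6, each = 4L)

  perms <- matrix(0L, n_candidates, 24L)
  with_seed(seed, {
    for (i in seq_len(n_candidates)) {
      perms[i, ] <- sample(used)
    }
  })
  pos_index <- matrix(match(perms, used), nrow(perms))   # values 1..24
  scores <- numeric(n_candidates)
  chunk <- 20000L
  for (lo in seq(1L, n_candidates, by = chunk)) {
    hi <- min(n_candidates, lo + chunk - 1L)
    idx <- pos_index[lo:hi, , drop = FALSE]
    nb <- hi - lo + 1L
    sds <- matrix(0, nb, length(variables))
    for (v in seq_along(variables)) {
      vals <- matrix(M[idx, v], nb, 24L)
      bm <- sapply(1:6, function(b) {
        rowMeans(vals[, block_of == b, drop = FALSE])
      })
      if (nb == 1L) bm <- matrix(bm, 1L)
      mu <- rowMeans(bm)
      sds[, v] <- sqrt(rowSums((bm - mu)^2) / 5)
    }
    scores[lo:hi] <- if (aggregate == "mean") rowMeans(sds) else
      apply(sds, 1L, max)
  }
  ord <- order(scores)
  structure(list(permutations = perms, scores = scores, order = ord,
                 used = used, variables = variables, aggregate = aggregate,
                 seed = as.integer(seed), n_candidates = n_candidates,
                 chamber = as.integer(chamber), sc_norm = sc_norm),
            class = "ccc_scheme_search")
}

#' @export
print.ccc_scheme_search <- function(x, ...) {
  cat(sprintf("Randomisation search: %d candidates, best score %.6g\n",
              x$n_candidates, x$scores[x$order[1]]))
  invisible(x)
}

.blocks_from_perm <- function(perm) {
  unname(split(as.integer(perm), rep(1:6, each = 4L)))
}

#' Select the final randomisation scheme (location-effect check)
#'
#' Walks the ranked candidates in ascending score order and returns the
#' first whose allocation blocks show no significant location effect: a
#' one-way ANOVA of each variable across the 6 blocks (on the normalised
#' systematic-control plates) must give `p > alpha` for every variable.
#'
#' @param search A `ccc_scheme_search` from [search_schemes()].
#' @param alpha Significance level of the location check (default 0.05);
#'   `alpha = 0` disables the filter.
#' @param max_check Maximum number of ranked candidates to test.
#' @return An object of class `ccc_scheme`: `chamber`, `blocks` (list of 6
#'   position vectors), `score`, `anova_p` (named per variable), `rank`,
#'   `seed`, `n_candidates`.
#' @export
select_scheme <- function(search, alpha = 0.05, max_check = 1000L) {
  stopifnot(inherits(search, "ccc_scheme_search"))
  sc <- search$sc_norm
  best_p <- NULL
  n_try <- min(max_check, search$n_candidates)
  for (k in seq_len(n_try)) {
    i <- search$order[k]
    perm <- search$permutations[i, ]
    block <- rep(1:6, each = 4L)[match(sc$allocation, perm)]
    pvals <- vapply(search$variables, function(v) {
      fit <- stats::lm(sc[[v]] ~ factor(block))
      stats::anova(fit)[["Pr(>F)"]][1]
    }, numeric(1))
    if (is.null(best_p) || min(pvals) > min(best_p)) best_p <- pvals
    if (alpha == 0 || all(pvals > alpha)) {
      scheme <- structure(list(chamber = search$chamber,
                               blocks = .blocks_from_perm(perm),
                               score = search$scores[i],
                               anova_p = pvals, rank = k,
                               seed = search$seed,
                               n_candidates = search$n_candidates),
                          class = "ccc_scheme")
      .check_scheme(scheme, search$used)
      return(scheme)
    }
  }
  stop("no candidate scheme passed the location check within ", n_try,
       " candidates; best per-variable p-values: ",
       paste(sprintf("%s=%.4f", names(best_p), best_p), collapse = ", "))
}

.check_scheme <- function(scheme, used) {
  pos <- unlist(scheme$blocks)
  if (length(scheme$blocks) != 6L || any(lengths(scheme$blocks) != 4L)) {
    stop("scheme must hold 6 blocks of 4 positions")
  }
  if (anyDuplicated(pos)) stop("scheme blocks are not disjoint")
  if (!all(pos %in% used)) stop("scheme uses positions outside the layout")
  invisible(scheme)
}

#' @export
print.ccc_scheme <- function(x, ...) {
  cat(sprintf("Randomisation scheme (chamber %d): score %.6g, rank %d\n",
              x$chamber, x$score, x$rank))
  for (b in seq_along(x$blocks)) {
    cat(sprintf("  block %d: %s\n", b, paste(x$blocks[[b]], collapse = " ")))
  }
  invisible(x)
}

#' Serialise / read a randomisation scheme as JSON
#' @param scheme A `ccc_scheme`.
#' @param path File path.
#' @return `read_scheme_json` returns a `ccc_scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "ccc_scheme"))
  jsonlite::write_json(
    list(chamber = scheme$chamber, blocks = scheme$blocks,
         score = scheme$score, anova_p = as.list(scheme$anova_p),
         rank = scheme$rank, seed = scheme$seed,
         n_candidates = scheme$n_candidates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(chamber = as.integer(x$chamber),
                 blocks = lapply(seq_len(nrow(x$blocks) %||% 6L), function(i) {
                   if (is.matrix(x$blocks)) as.integer(x$blocks[i, ])
                   else as.integer(x$blocks[[i]])
                 }),
                 score = x$score, anova_p = unlist(x$anova_p),
                 rank = x$rank, seed = as.integer(x$seed),
                 n_candidates = as.integer(x$n_candidates)),
            class = "ccc_scheme")
}

#' Build a random counterbalanced rotation (Latin square)
#'
#' Rotates each sample through every allocation block across the days:
#' a random 6x6 Latin square obtained by randomly permuting the rows,
#' columns and symbols of the cyclic square (deterministic per seed).
#'
#' @param n_days Number of days / blocks / samples (6).
#' @param seed Integer seed.
#' @return A `ccc_rotation` matrix (rows = days, columns = samples).
#' @export
build_rotation <- function(n_days = 6L, seed = 1L) {
  n <- as.integer(n_days)
  base <- unclass(default_rotation(n))
  with_seed(seed, {
    rp <- sample(n); cp <- sample(n); sp <- sample(n)
    m <- matrix(sp[base[rp, cp]], n, n)
  })
  structure(m, class = c("ccc_rotation", class(m)))
}
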