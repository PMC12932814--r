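#' Circular region-of-interest mask
#'
#' A pixel is included iff `r_lo_pct <= 100 * dist(pixel, centre) /
#' plate_radius < r_hi_pct`, i.e. the annulus is closed at the inner and
#' open at the outer radius.
#'
#' @param image A [ccc_image()].
#' @param roi Length-2 numeric `c(r_lo_pct, r_hi_pct)`, percentages of the
#'   plate radius with `0 <= lo < hi <= 100`.
#' @return Logical matrix with the image's dimensions.
#' @export
roi_mask <- function(image, roi = c(0, 100)) {
  stopifnot(inherits(image, "ccc_image"))
  if (length(roi) != 2L || !is.numeric(roi)) stop("roi must be c(lo, hi)")
  if (!(roi[1] >= 0 && roi[1] < roi[2] && roi[2] <= 100)) {
    stop("roi percentages must satisfy 0 <= lo < hi <= 100")
  }
  d <- .radius_map(nrow(image$pixels), ncol(image$pixels), image$centre)
  pct <- 100 * d / image$plate_radius
  pct >= roi[1] & pct < roi[2]
}

#' Grey-level co-occurrence matrix of a fingerprint region
#'
#' Quantises the 8-bit image linearly to `levels` grey levels and
#' accumulates co-occurring pairs over the given pixel offsets (default:
#' one-pixel horizontal and vertical displacement), counting each pair in
#' both directions (symmetrised) and normalising to total probability 1.
#' Only pairs with both pixels inside the ROI mask contribute.
#'
#' @param image A [ccc_image()].
#' @param roi ROI percentages passed to [roi_mask()], or `NULL` for the
#'   whole raster.
#' @param levels Number of grey levels after quantisation (>= 2).
#' @param offsets List of integer `c(dr, dc)` displacements.
#' @return An object of class `ccc_glcm` with elements `p` (G x G joint
#'   probability matrix), `levels`, `offsets`, marginals `px`, `py` and
#'   marginal moments `mu_x`, `mu_y`, `sd_x`, `sd_y`.
#' @export
compute_glcm <- function(image, roi = c(0, 100), levels = 32L,
                         offsets = list(c(0L, 1L), c(1L, 0L))) {
  stopifnot(inherits(image, "ccc_image"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  mask <- if (is.null(roi)) {
    matrix(TRUE, nrow(image$pixels), ncol(image$pixels))
  } else {
    roi_mask(image, roi)
  }
  q <- pmin(floor(image$pixels / 256 * levels), levels - 1L)
  storage.mode(q) <- "integer"
  G <- levels
  counts <- numeric(G * G)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    dr <- as.integer(off[1]); dc <- as.integer(off[2])
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    idx <- a[ok] * G + b[ok] + 1L
    counts <- counts + tabulate(idx, nbins = G * G)
  }
  C <- matrix(counts, G, G, byrow = TRUE)  # row i = first pixel level
  total_pairs <- sum(C)
  if (total_pairs < 1) stop("ROI contains fewer than 2 valid pixel pairs")
  C <- C + t(C)
  p <- C / sum(C)
  px <- rowSums(p); py <- colSums(p)
  g <- 0:(G - 1)
  mu_x <- sum(g * px); mu_y <- sum(g * py)
  glcm <- list(p = p, levels = G, offsets = offsets,
               px = px, py = py, mu_x = mu_x, mu_y = mu_y,
               sd_x = sqrt(sum((g - mu_x)^2 * px)),
               sd_y = sqrt(sum((g - mu_y)^2 * py)))
  class(glcm) <- "ccc_glcm"
  glcm
}

#' @export
print.ccc_glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, %d offset(s), sum(p) = %.6f\n",
              x$levels, length(x$offsets), sum(x$p)))
  invisible(x)
}

#' Second-order texture variables of a co-occurrence matrix
#'
#' Computes the 15 texture variables used by the fingerprint evaluation.
#' The four analysis variables are defined as:
#' \describe{
#'   \item{entropy}{`-sum(p * ln p)` (natural log, `0 ln 0 := 0`):
#'     randomness of the grey-level pair distribution.}
#'   \item{cluster_shade}{`sum((i + j - mu_x - mu_y)^3 * p)`: skewness /
#'     asymmetry of the pattern.}
#'   \item{diagonal_moment}{`sum(|i - j| * (i + j - mu_x - mu_y) * p)`:
#'     sign-carrying roughness; positive when bright areas are rough and
#'     dark areas smooth.}
#'   \item{kappa}{chance-corrected diagonal agreement
#'     `(P_o - P_e) / (1 - P_e)` with `P_o = sum(p[i,i])`,
#'     `P_e = sum(px * py)`: consistency of the fingerprint. A degenerate
#'     single-level matrix (`P_e = 1`) yields 0 with a warning.}
#' }
#' The remaining 11 follow the standard Haralick second-order definitions.
#'
#' @param glcm A `ccc_glcm` from [compute_glcm()].
#' @return Named numeric vector of length 15.
#' @export
texture_features <- function(glcm) {
  stopifnot(inherits(glcm, "ccc_glcm"))
  p <- glcm$p
  G <- glcm$levels
  g <- 0:(G - 1)
  I <- matrix(g, G, G)        # row index value
  J <- matrix(g, G, G, byrow = TRUE)
  mu_x <- glcm$mu_x; mu_y <- glcm$mu_y
  pos <- p > 0
  ent <- -sum(p[pos] * log(p[pos]))
  dev <- I + J - mu_x - mu_y

  # sum / difference distributions
  k_sum <- 0:(2 * G - 2)
  agg_s <- rowsum(as.numeric(p), group = as.integer(I + J))
  p_sum_full <- numeric(length(k_sum))
  p_sum_full[as.integer(rownames(agg_s)) + 1L] <- agg_s[, 1]
  k_diff <- 0:(G - 1)
  agg_d <- rowsum(as.numeric(p), group = as.integer(abs(I - J)))
  p_diff_full <- numeric(length(k_diff))
  p_diff_full[as.integer(rownames(agg_d)) + 1L] <- agg_d[, 1]

  sum_avg <- sum(k_sum * p_sum_full)
  sp <- p_sum_full > 0
  dp <- p_diff_full > 0
  diff_mean <- sum(k_diff * p_diff_full)

  P_o <- sum(diag(p))
  P_e <- sum(glcm$px * glcm$py)
  if (1 - P_e < 1e-12) {
    warning("degenerate single-level co-occurrence matrix; kappa set to 0")
    kap <- 0
  } else {
    kap <- (P_o - P_e) / (1 - P_e)
  }

  corr <- if (glcm$sd_x > 0 && glcm$sd_y > 0) {
    sum((I - mu_x) * (J - mu_y) * p) / (glcm$sd_x * glcm$sd_y)
  } else 0

  c(
    entropy = ent,
    cluster_shade = sum(dev^3 * p),
    diagonal_moment = sum(abs(I - J) * dev * p),
    kappa = kap,
    energy = sum(p^2),
    contrast = sum((I - J)^2 * p),
    correlation = corr,
    variance = sum((I - mu_x)^2 * p),
    inverse_difference_moment = sum(p / (1 + (I - J)^2)),
    sum_average = sum_avg,
    sum_variance = sum((k_sum - sum_avg)^2 * p_sum_full),
    sum_entropy = -sum(p_sum_full[sp] * log(p_sum_full[sp])),
    difference_variance = sum((k_diff - diff_mean)^2 * p_diff_full),
    difference_entropy = -sum(p_diff_full[dp] * log(p_diff_full[dp])),
    cluster_prominence = sum(dev^4 * p)
  )
}

#' Texture variables of a fingerprint image
#'
#' Convenience wrapper: [compute_glcm()] then [texture_features()].
#'
#' @inheritParams compute_glcm
#' @return Named numeric vector of the 15 texture variables.
#' @export
compute_texture_features <- function(image, roi = c(0, 100), levels = 32L,
                                     offsets = list(c(0L, 1L), c(1L, 0L))) {
  texture_features(compute_glcm(image, roi = roi, levels = levels,
                                offsets = offsets))
}
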