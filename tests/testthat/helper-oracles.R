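# Independent oracles and fixture builders used across the suite.
# These deliberately use naive enumeration so they cannot share defects
# with the package's vectorised implementations.

# wrap a small grey-value matrix as a fingerprint whose plate disc covers
# the whole raster (centre = matrix centre, generous radius)
as_test_image <- function(mat, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(sqrt(sum((dim(mat) / 2)^2))) + 2
  ccc_image(mat, centre = (dim(mat) + 1) / 2, plate_radius = radius)
}

# brute-force symmetrised GLCM by explicit double loop over pixels
brute_glcm <- function(pixels, levels, offsets, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  q <- matrix(pmin(floor(pixels / 256 * levels), levels - 1), nrow(pixels))
  C <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      for (off in offsets) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
            mask[r, c] && mask[r2, c2]) {
          i <- q[r, c] + 1; j <- q[r2, c2] + 1
          C[i, j] <- C[i, j] + 1
          C[j, i] <- C[j, i] + 1
        }
      }
    }
  }
  C / sum(C)
}

# brute-force endpoint count: 3x3 neighbourhood scan
brute_endpoints <- function(skel) {
  n <- 0L
  nr <- nrow(skel); nc <- ncol(skel)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!skel[r, c]) next
      deg <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc]) {
          deg <- deg + 1L
        }
      }
      if (deg == 1L) n <- n + 1L
    }
  }
  n
}

# sequential (Type-I) sums of squares by explicit projection matrices,
# for small fixtures only
projection_ss <- function(data, response, terms) {
  y <- data[[response]]
  n <- length(y)
  X <- matrix(1, n, 1)
  ss <- numeric(length(terms))
  fitted_prev <- drop(X %*% solve(crossprod(X), crossprod(X, y)))
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+"))), data)
    P <- mm %*% MASS::ginv(crossprod(mm)) %*% t(mm)
    fitted <- drop(P %*% y)
    ss[k] <- sum((fitted - fitted_prev)^2)
    fitted_prev <- fitted
  }
  resid_ss <- sum((y - fitted_prev)^2)
  list(ss = stats::setNames(ss, terms), resid_ss = resid_ss)
}

# draw a set of pixel paths into a logical matrix
draw_pixels <- function(nr, nc, coords) {
  m <- matrix(FALSE, nr, nc)
  for (rc in coords) m[rc[1], rc[2]] <- TRUE
  m
}

# horizontal run of `len` pixels starting at (r, c)
hrun <- function(r, c, len) lapply(seq_len(len) - 1L, function(k) c(r, c + k))

# 8-connected component count by naive flood fill
count_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!m[r0, c0] || seen[r0, c0]) next
    n <- n + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- rc[1] + dr; cc <- rc[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

# a small systematic-control table: one value per (day, allocation)
make_sc_table <- function(days = 1:3, positions = 1:24, seed = 1,
                          position_effect = NULL) {
  grid <- expand.grid(day = days, allocation = positions)
  vars <- analysis_variables()
  withr::with_seed(seed, {
    for (v in vars) {
      base <- 10 + 5 * match(v, vars)
      grid[[v]] <- base + rnorm(nrow(grid))
      if (!is.null(position_effect)) {
        grid[[v]] <- grid[[v]] + position_effect[grid$allocation]
      }
    }
  })
  grid
}
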