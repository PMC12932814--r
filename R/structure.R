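#' Binarise the crystal structure of a fingerprint
#'
#' Local (adaptive) mean thresholding: a pixel is foreground when it
#' exceeds the mean of its square neighbourhood by `offset` grey values.
#' The local mean is computed over ROI pixels only, so a smooth
#' illumination gradient or the plate boundary does not bias the
#' statistics; the ROI mask (default the inner 0-90% of the plate radius,
#' where needles live) is applied before any thresholding statistics.
#'
#' @param image A [ccc_image()].
#' @param roi ROI percentages (see [roi_mask()]); default `c(0, 90)`.
#' @param window Side length (px) of the local-mean window; default
#'   `plate_radius / 8`.
#' @param offset Grey-value offset above the local mean required for
#'   foreground membership.
#' @return Logical matrix: `TRUE` = needle pixel. An empty foreground
#'   triggers a warning (structure features will be all zero).
#' @export
binarise <- function(image, roi = c(0, 90), window = NULL, offset = 10) {
  stopifnot(inherits(image, "ccc_image"))
  mask <- if (is.null(roi)) {
    matrix(TRUE, nrow(image$pixels), ncol(image$pixels))
  } else {
    roi_mask(image, roi)
  }
  if (is.null(window)) window <- max(5, round(image$plate_radius / 8))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  img <- image$pixels * 1.0
  img[!mask] <- 0
  box <- matrix(1, window, window)
  num <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), box,
                                             boundary = 0))
  den <- EBImage::imageData(EBImage::filter2(EBImage::Image(mask * 1.0), box,
                                             boundary = 0))
  localmean <- num / pmax(den, 1e-9)
  fg <- mask & (image$pixels > localmean + offset)
  if (!any(fg)) warning("empty foreground: no needle pixels detected")
  fg
}

# shift a logical matrix by (dr, dc), padding with FALSE:
# out[r, c] = m[r + dr, c + dc]
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

.neighbour_offsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                           c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

# 8-neighbour count of every TRUE pixel
.neighbour_count <- function(m) {
  cnt <- matrix(0L, nrow(m), ncol(m))
  for (off in .neighbour_offsets) {
    cnt <- cnt + .shift(m, off[1], off[2])
  }
  cnt
}

#' Skeletonise a binary needle map
#'
#' Topology-preserving Zhang-Suen thinning to a 1-pixel-wide,
#' 8-connected skeleton.
#'
#' @param binary Logical (or 0/1) matrix of needle pixels.
#' @return Logical matrix: the skeleton.
#' @export
skeletonise <- function(binary) {
  m <- binary != 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      P <- lapply(.neighbour_offsets, function(o) .shift(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        A <- A + (!P[[k]] & P[[if (k == 8) 1 else k + 1]])
      }
      cond <- m & B >= 2 & B <= 6 & A == 1L
      if (sub == 1) {
        cond <- cond & !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      } else {
        cond <- cond & !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeleton endpoints
#'
#' Endpoint pixels are skeleton pixels with exactly one 8-neighbour on the
#' skeleton (degree 1).
#'
#' @param skeleton Logical matrix from [skeletonise()].
#' @return Logical matrix marking endpoint pixels.
#' @export
skeleton_endpoints <- function(skeleton) {
  skeleton & .neighbour_count(skeleton) == 1L
}

#' Decompose a skeleton into needle segments
#'
#' Needles are maximal skeleton paths between nodes, where a node is a
#' pixel whose skeleton degree differs from 2 (an endpoint or a branch
#' point). Branch pixels are shared between the segments meeting there;
#' pure cycles (all pixels of degree 2) are returned as one closed
#' segment. Path length is the sum of inter-pixel steps (1 for
#' 4-neighbour, sqrt(2) for diagonal moves); `mean_width` is the average
#' of twice the Euclidean distance-transform of the binary map sampled
#' along the path (`NA` when `binary` is not supplied).
#'
#' @param skeleton Logical skeleton matrix.
#' @param binary Optional binary needle map used for width estimation.
#' @return A data frame of class `ccc_segments` with one row per segment:
#'   `segment`, `length`, `n_pixels`, `mean_width`, `closed`.
#' @export
decompose_needles <- function(skeleton, binary = NULL) {
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  pix <- which(skeleton)
  empty <- data.frame(segment = integer(), length = numeric(),
                      n_pixels = integer(), mean_width = numeric(),
                      closed = logical())
  class(empty) <- c("ccc_segments", "data.frame")
  if (!length(pix)) return(empty)

  dm <- if (!is.null(binary)) {
    EBImage::imageData(EBImage::distmap(EBImage::Image(binary * 1.0)))
  } else NULL

  deg <- .neighbour_count(skeleton)
  # neighbour lookup by linear index
  nbrs <- function(i) {
    r <- ((i - 1L) %% nr) + 1L
    c0 <- ((i - 1L) %/% nr) + 1L
    out <- integer(0)
    for (off in .neighbour_offsets) {
      rr <- r + off[1]; cc <- c0 + off[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skeleton[rr, cc]) {
        out <- c(out, (cc - 1L) * nr + rr)
      }
    }
    out
  }
  step_len <- function(i, j) {
    dr <- abs(((i - 1L) %% nr) - ((j - 1L) %% nr))
    dc <- abs(((i - 1L) %/% nr) - ((j - 1L) %/% nr))
    if (dr + dc == 2L) sqrt(2) else 1
  }
  path_row <- function(path, closed, id) {
    len <- 0
    if (length(path) > 1L) {
      for (k in 2:length(path)) len <- len + step_len(path[k - 1L], path[k])
    }
    w <- if (is.null(dm)) NA_real_ else mean(2 * dm[path])
    data.frame(segment = id, length = len, n_pixels = length(path),
               mean_width = w, closed = closed)
  }

  nodes <- pix[deg[pix] != 2L]
  used_step <- new.env(hash = TRUE)  # directed first/last steps already walked
  covered <- logical(nr * nc)
  segs <- list()
  id <- 0L

  for (p in nodes) {
    covered[p] <- TRUE
    if (deg[p] == 0L) {          # isolated pixel: degenerate 1-px segment
      id <- id + 1L
      segs[[id]] <- path_row(p, closed = FALSE, id = id)
      next
    }
    for (q in nbrs(p)) {
      key <- paste0(p, ">", q)
      if (!is.null(used_step[[key]])) next
      path <- c(p, q)
      used_step[[key]] <- TRUE
      prev <- p; cur <- q
      while (deg[cur] == 2L) {
        covered[cur] <- TRUE
        nx <- nbrs(cur)
        nx <- nx[nx != prev]
        if (!length(nx)) break     # defensive: dangling degree-2 pixel
        prev <- cur; cur <- nx[1L]
        path <- c(path, cur)
      }
      covered[cur] <- TRUE
      used_step[[paste0(cur, ">", prev)]] <- TRUE
      id <- id + 1L
      segs[[id]] <- path_row(path, closed = FALSE, id = id)
    }
  }

  # pure cycles: degree-2 pixels never reached from any node
  for (p in pix) {
    if (covered[p] || deg[p] != 2L) next
    path <- p
    covered[p] <- TRUE
    prev <- p
    cur <- nbrs(p)[1L]
    while (cur != p && !covered[cur]) {
      covered[cur] <- TRUE
      path <- c(path, cur)
      nx <- nbrs(cur)
      nx <- nx[nx != prev]
      prev <- cur
      cur <- nx[1L]
    }
    path <- c(path, p)   # close the loop for the length sum
    id <- id + 1L
    row <- path_row(path, closed = TRUE, id = id)
    row$n_pixels <- length(path) - 1L
    segs[[id]] <- row
  }

  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("ccc_segments", "data.frame")
  out
}

#' Default needle length-bin edges
#'
#' 15 right-open bins sharing one geometric relative-width convention with
#' the two printed edges: with `r = 22 / 19.2`, the finite edges are
#' `19.2 * r^(k - 13)` for `k = 1..14`, so bin 14 is `[19.2, 22)` (the
#' l220 count) and bin 15 is `[22, Inf)` (the l250 count).
#'
#' @return Numeric vector of 16 break points (`0 ... Inf`).
#' @export
default_length_edges <- function() {
  r <- 22 / 19.2
  edges <- c(0, 19.2 * r^((1:14) - 13), Inf)
  edges[14] <- 19.2   # pin the printed edges exactly (no fp drift)
  edges[15] <- 22
  edges
}

#' Default needle width-bin edges (15 geometric bins over 1-12 px)
#' @return Numeric vector of 16 break points.
#' @export
default_width_edges <- function() {
  c(0, exp(seq(log(1), log(12), length.out = 14)), Inf)
}

.bin_names <- function(edges, prefix) {
  upper <- edges[-1]
  nm <- sprintf("%s%03d", prefix, pmin(999, round(10 * upper[-length(upper)])))
  c(nm, sprintf("%s%03d", prefix, round(10 * edges[length(edges) - 1]) + 30))
}

# the method's conventional names for the top two length bins
.length_bin_names <- function(edges) {
  nm <- .bin_names(edges, "l")
  n <- length(nm)
  if (isTRUE(all.equal(edges[n], 19.2)) && isTRUE(all.equal(edges[n + 1], 22))) {
    nm[n] <- "l220"
    nm[n + 1] <- "l250"
  }
  nm
}

#' Structure variables of a decomposed skeleton
#'
#' `lend` is the number of skeleton endpoint pixels (degree-1 pixels).
#' Segment lengths and mean widths are histogrammed into 15 right-open
#' bins each (the top bin is `[max_edge, Inf)`); with the default edges
#' the top two length bins are `l220 = [19.2, 22)` and `l250 = [22, Inf)`.
#' Segments shorter than `prune` pixels (spur artefacts of thinning) are
#' discarded before binning.
#'
#' @param segments A `ccc_segments` data frame from [decompose_needles()].
#' @param skeleton The skeleton the segments came from.
#' @param length_edges,width_edges Bin break points (16 values each); see
#'   [default_length_edges()] and [default_width_edges()].
#' @param prune Minimum segment length (px) retained; default 2.
#' @return Named numeric vector: `lend`, `n_needles`, 15 length-bin counts
#'   (`l...`, ending in `l220`, `l250`) and 15 width-bin counts (`w...`).
#' @export
structure_features <- function(segments, skeleton,
                               length_edges = default_length_edges(),
                               width_edges = default_width_edges(),
                               prune = 2) {
  stopifnot(is.data.frame(segments))
  if (length(length_edges) != 16L || length(width_edges) != 16L) {
    stop("edge vectors must contain 16 break points (15 bins)")
  }
  lend <- sum(skeleton_endpoints(skeleton))
  keep <- segments[segments$length >= prune, , drop = FALSE]
  lbin <- table(cut(keep$length, breaks = length_edges, right = FALSE))
  lnames <- .length_bin_names(length_edges)
  wvals <- keep$mean_width
  wvals <- wvals[is.finite(wvals)]
  wbin <- table(cut(wvals, breaks = width_edges, right = FALSE))
  wnames <- .bin_names(width_edges, "w")
  out <- c(lend = as.numeric(lend), n_needles = nrow(keep),
           stats::setNames(as.numeric(lbin), lnames),
           stats::setNames(as.numeric(wbin), wnames))
  out
}

#' Structure variables of a fingerprint image
#'
#' Convenience wrapper: [binarise()] (ROI 0-90%), [skeletonise()],
#' [decompose_needles()], [structure_features()].
#'
#' @inheritParams binarise
#' @inheritParams structure_features
#' @return Named numeric vector as for [structure_features()].
#' @export
compute_structure_features <- function(image, roi = c(0, 90), window = NULL,
                                       offset = 10,
                                       length_edges = default_length_edges(),
                                       width_edges = default_width_edges(),
                                       prune = 2) {
  fg <- binarise(image, roi = roi, window = window, offset = offset)
  sk <- skeletonise(fg)
  segs <- decompose_needles(sk, binary = fg)
  structure_features(segs, sk, length_edges = length_edges,
                     width_edges = width_edges, prune = prune)
}
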